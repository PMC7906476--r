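# dsynet

Mechanism-driven prediction and interpretation of anti-cancer drug
combination synergy.

## The problem

High-throughput screens measure the synergy of drug pairs on cancer cell
lines, but the space of combinations is far too large to screen
exhaustively. Purely structure-based predictors are hard to interpret
because molecular descriptors have no direct cellular meaning. `dsynet`
takes the mechanism-driven route: a drug is represented by what it does to
the proteome, a cell line by which genes it depends on, and the model then
learns how two perturbation profiles interact with a cell's dependency
profile to produce synergy — so every input feature corresponds to a gene
and every prediction can be attributed back to genes and pathways.

The package is aimed at computational biologists who want a tested,
self-contained implementation of this modelling approach: every stage runs
end-to-end on generated synthetic data, with no external downloads.

## The model

**Drug representation.** Binary drug–target vectors *e* over a gene panel
are diffused over a confidence-weighted protein–protein association
network by random walk with restart,

    r = α W r + (1 − α) e,

where *W* is the column-stochastic transition matrix of the network and
α = 1 − restart rate (default α = 0.5). The stationary distribution *r*
scores every gene's proximity to the drug's targets — a genome-wide
drug-effect profile.

**Cell-line representation.** Per-gene dependency (loss-of-function
essentiality) and/or expression profiles on the same gene panel, imputed
by chained linear regression and z-scored per gene.

**Predictor.** Each sample is a genes × k matrix (k = 3: drug A, drug B,
cell feature column; k = 4 with both dependency and expression). A shared
single-layer reduction maps the 2401-gene axis to 512 latent dimensions;
a transformer encoder applies scaled dot-product self-attention,
softmax(QKᵀ/√d)V, over the feature columns — with the positional encoding
removed, because column order carries no meaning — and a fully connected
head emits the synergy score. Two variants append per-drug chemical
information before the head: classical descriptors (ECFP circular
fingerprint, physicochemical properties, toxicophores) or graph
convolutional neural fingerprints built from
softmax(D⁻¹(A + I)H W) layers over the molecular graph
(62-dimensional multi-hot atom features, 6-dimensional bond features).

**Evaluation.** Three cold-start protocols: leave-combination-out (nested
five-fold CV over unordered drug pairs, training doubled by drug A/B
swapping), leave-cell-line-out and leave-drug-out (affinity-propagation
clusters held out wholesale). Metrics: MSE, Pearson, Spearman, and
ROC-AUC / PR-AUC after binarizing at synergy > 30. Untested combinations
are prioritized by per-cell-line z-scores of predicted synergy.

**Interpretation (SA-GSEA).** Per-gene attributions of a single
prediction are estimated by expected gradients against a k-means-summarized
background (10 repeats averaged; attributions sum to the prediction minus
the background expectation). Genes ranked by attribution feed a weighted
Kolmogorov–Smirnov enrichment statistic with a set-resampling permutation
null.

## Worked example

```r
library(dsynet)

# a synthetic study: network, drugs, cells, synergy with a planted mechanism
study <- simulateStudy(synthConfig(nGenes = 150, nDrugs = 8, nCells = 5, seed = 7))
dep   <- standardizeFeatures(imputeMissing(study$dependency))

plan <- splitLeaveCombinationOut(study$records, nFolds = 5, seed = 7)
cfg  <- modelConfig(panelSize = 150, reducedDim = 32, nHeads = 4, ffDim = 64,
                    dropout = 0.1, headHidden = c(64, 32), nTokens = 3,
                    seed = 7, lr = 2e-3, batchSize = 64, epochs = 100)
fit <- trainFold(study$records, plan@folds[[1]], study$profiles, dep, config = cfg)
str(fit$metrics)
#> List of 7
#>  $ mse      : num 319
#>  $ pearson  : num 0.978
#>  $ spearman : num 0.98
#>  $ rocAuc   : num 1
#>  $ prAuc    : num 1
#>  $ threshold: num 30
#>  $ nPositive: int 5
```

Held-out drug pairs are predicted with Pearson r ≈ 0.98 here: the model
recovers the planted propagation-times-dependency mechanism from data it
never saw. Explaining the strongest predicted synergy:

```r
samples <- buildSampleSet(synergyRecords(study$records), study$profiles, dep)
bg      <- backgroundCentroids(samples, k = 15, seed = 7)
idx     <- which.max(study$records$score)
report  <- computeAttributions(fit$model, samples[[idx]], bg,
                               attributionConfig(nRepeats = 3,
                                                 integrationSteps = 64, seed = 7))
report
#> AttributionReport: 150 genes x 3 columns; f(x) = 90.46, E[f(bg)] = -47.38, sum(attr) = 138.2

enr <- saGsea(report, study$geneSets, nPermutations = 500, seed = 7)
head(enr[, c("geneSet", "es", "nes", "p", "padj")], 3)
#>      geneSet        es      nes           p       padj
#>  planted_top 0.7430075 1.726074 0.001996008 0.01996008
#>    random_07 0.4967369 1.153965 0.227544910 0.62275449
#>    random_03 0.4892057 1.136469 0.241516966 0.62275449
```

The attribution report is additive (138.2 ≈ 90.46 − (−47.38)), and the
gene set planted by the generator is the only significantly enriched one.

A command-line driver wrapping the same functions ships in
`inst/cli/dsynet.R` with stages
`simulate | propagate | train | evaluate | predict | explain`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dsynet.R", package = "dsynet"))')" \
    train --config run.yaml --seed 1 --out out/
```

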