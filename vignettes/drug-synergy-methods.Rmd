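---
title: "Methods: mechanism-driven synergy prediction and its interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanism-driven synergy prediction and its interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`dsynet`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic experiments do and do not demonstrate.

## 1. Network propagation of drug targets

A drug's observed target set is a sparse binary vector `e` over the gene
panel. Its cellular effect is modelled as the stationary distribution of
a random walk with restart on the protein–protein association network:
`r = alpha * W %*% r + (1 - alpha) * e`, solved either directly
(`(I - alpha W) r = (1 - alpha) e`, sparse LU) or by power iteration.

Design choices the underlying mathematics leaves open, and how this
package resolves them:

* **Column-stochastic `W`.** The confidence-weighted adjacency is
  normalized per column, so `W[i, j]` is the probability of stepping from
  gene *j* to gene *i*. With a symmetric adjacency, row normalization is
  the transpose convention; column-stochasticity is chosen because it
  makes `r` a probability distribution (mass conservation,
  `sum(r) = 1`), which the test suite asserts to 1e-8.
* **Seed normalization.** Seeds are normalized to sum 1 before
  propagation so profiles of drugs with different target counts are
  comparable; raw mode is available via
  `propagationConfig(normalizeSeed = FALSE)`.
* **Dangling genes** (no incident edges, e.g. synthetic padding) get a
  self-loop column by default, preserving mass conservation. A
  `teleport` policy (zero column, mass decays) exists for users who
  prefer absorbing behaviour.
* **`alpha` (unitless, in [0, 1))** defaults to 0.5, the
  validation-selected value in the study design this package follows;
  it balances local target fidelity against network smoothing. At
  `alpha = 0` propagation is the identity.
* **Solver.** Direct sparse solve is the default (exact to solver
  tolerance, fine up to tens of thousands of genes); power iteration
  (tol 1e-8, max 1000 iterations, structured non-convergence error) is
  the alternative for very large panels. The two agree within 1e-6 in
  the cross-check test.
* STRING-style confidences are used as-is (no probability transform);
  an edge-confidence cutoff is available and defaults to 0.

## 2. Cell-line features and the gene panel

The gene panel is the union of drug-target genes and an annotated cancer
gene list (targets first, then cancer-only genes, alphabetical within
groups), truncated or padded to a fixed size (default 2401, the published
panel size). Padding with placeholder genes is permitted only in
synthetic mode, so full-scale tensor shapes remain testable without
proprietary gene lists; padding genes carry all-zero features and a
self-loop in the network.

Missing feature entries are imputed by chained linear regression:
initialize with gene-row means, then regress each incomplete gene row on
the most correlated complete rows (default 5 predictors, ordinary least
squares) and refresh the missing entries, iterating to `tol = 1e-4` or
`maxIter = 10`. With fixed complete-row predictors a single sweep is
already a fixed point; the iteration guard matters only for pathological
inputs. Observed entries are never modified, and a gene with fewer than
two observations is a structured error naming the gene. After
imputation, each gene row is z-scored with the *population* SD across
cell lines (zero-variance rows map to zero and are flagged). Scaling is
per gene, not per cell line, because dependency and expression values are
comparable across cells for a fixed gene, not across genes.

## 3. The synergy model

One sample is a `genes x k` matrix: propagated profiles of drug A and
drug B, then one (k = 3) or two (k = 4) cell feature columns.

* **Reduction.** A single linear map (2401 → 512 by default), *shared
  across columns*, so drugs and cells live in one latent gene space.
* **Encoder.** A transformer encoder whose *tokens are the k feature
  columns*. Scaled dot-product attention `softmax(Q K^T / sqrt(d)) V`
  (row-stochastic weights, asserted at 1e-6), multi-head (8 heads by
  default), residual + layer normalization, ReLU feed-forward, residual
  + layer normalization. The positional encoding is removed: which drug
  is "A" and which "B" carries no information, and the encoder is
  consequently permutation-equivariant over tokens, which the test suite
  asserts directly. A configuration flag records the token layout; the
  alternative reading ("tokens = latent feature positions") would put
  512 tokens through quadratic-in-tokens attention and is not
  implemented — on CPU at package scale it is computationally
  indefensible, and the equivariance argument above favours column
  tokens.
* **Head.** Flattened encoder output (plus, in the CI/GNF variants, the
  two per-drug chemical feature vectors) through a ReLU MLP
  (default 2048, 512) to one scalar.
* **Defaults** standing in where the source design leaves hyperparameters
  unstated: 1 encoder layer, feed-forward width 512, dropout 0.2, Adam
  with learning rate 1e-4, batch 64. All are `modelConfig()` arguments.
* **Training.** Minibatch Adam on MSE of label-standardized scores
  (labels are z-scored inside `trainFold`; predictions return on the
  original scale). Pair-swap augmentation doubles the training portion
  only — the swapped copy of a test record never exists. Validation MSE
  is monitored on a held-out validation fold and the best-validation
  parameters are restored before test evaluation. Every run is fully
  seeded (initialization, shuffling, dropout); inference disables
  dropout and is bit-reproducible.
* The forward and backward passes are hand-written batched matrix
  algebra; analytic gradients are verified against central finite
  differences at 1e-5 relative error in the test suite, for parameters
  and for inputs (the input gradient drives attribution).

## 4. Molecular featurization

SMILES strings are canonicalized (OpenBabel) before featurization, so
graphs are pure functions of the molecule, not of the SMILES dialect.
Atom features (62 = 44 element one-hot + 6 degree + 5 implicit-H + 5
formal charge + aromatic + ring): the element vocabulary is 43 named
symbols plus "other"; degree clamps at 5, implicit hydrogens (derived
from standard valence, bond-order sum and charge) at 4, charge at ±2.
Bond features (6): order one-hot (single/double/triple/aromatic),
conjugation (both atoms carry a multiple/aromatic bond), ring
membership. Aromaticity comes from ring perception on the kekulized
structure.

The graph convolution is `activation(D^-1 (A + I) H W)` with a row-wise
softmax activation as the default and ReLU available by configuration.
Softmax-as-activation is unusual (it makes every node representation a
probability vector); it is implemented as specified but flagged here —
users composing deeper stacks may prefer `activation = "relu"`. Neural
fingerprints concatenate final node representations in canonical atom
order, zero-padded to `maxAtoms` (default 64).

Classical descriptors: ECFP4-equivalent circular fingerprint (radius 2)
folded from 4096 to 2048 bits by OR, eight OpenBabel physicochemical
properties (HBA1, HBA2, HBD, logP, MR, MW, nF, TPSA), and a
12-pattern toxicophore SMARTS set shipped as an editable TSV
(`inst/extdata/toxicophores.tsv`). SMARTS matching runs through the
OpenBabel command-line filter.

## 5. Evaluation protocols

* **Leave-combination-out**: distinct unordered pairs are shuffled
  (seeded) into five near-equal folds; all records of a pair travel
  together. Each fold is the test set once; one rotating fold of the
  remainder is validation, the rest training. This simplification of a
  full nested hyperparameter search (inner validation fold + declared
  default grid) keeps runs desk-scale; the splitter is deliberately
  independent of the model so a full nested search can be layered on.
* **Leave-cell-line-out**: cells are clustered by affinity propagation
  on their feature vectors; the largest cluster trains, everything else
  tests.
* **Leave-drug-out**: drugs are clustered on structural fingerprints;
  each of the smallest clusters (default 3) is held out in turn, and
  *every* record touching a held-out drug goes to test, keeping
  train:test near 4:1.

Affinity propagation is the standard responsibility/availability message
passing on negative squared Euclidean similarity, preference = median
off-diagonal similarity, damping 0.5, convergence after 50 stable
iterations. No jitter is added, so results are deterministic; perfectly
symmetric degenerate inputs break ties by index order. Cluster counts
are outcomes, not inputs — the protocol accepts whatever count emerges
(the full-scale study reports 4 cell and 5 drug clusters).

Metrics: MSE, Pearson, Spearman on raw scores; ROC-AUC (via pROC) and
trapezoidal PR-AUC (anchored at recall 0 / precision 1) after binarizing
at synergy > 30, the established positive-synergy cutoff. All metrics are
validated against brute-force reimplementations at 1e-10. Novel-pair
prioritization standardizes predicted scores within each cell line
(population SD; constant cells get z = 0; single-prediction cells are
flagged undefined and ranked last) and sorts by z with score-then-id tie
breaks.

## 6. SA-GSEA

Attributions are estimated with expected gradients: for explicand `x`
and background reference `b`, integrate the input gradient along
`b + alpha (x - b)` over a randomized-midpoint `alpha` grid
(`integrationSteps`, default 128), multiply by `x - b`, and average over
references and over `nRepeats = 10` independent repeats. The background
is a k-means summary of training samples (k = 25 by default; the source
design states no k). This estimator satisfies the additivity axiom up to
integration error; the suite asserts 5% relative additivity on trained
models and exactness on linear models. Exact Shapley values are
exponential in features and out of scope.

Enrichment uses the weighted Kolmogorov–Smirnov statistic: walking the
attribution-ranked list, set members add `|score|^p / sum(|score|^p)`
(p = 1 by default, the classic weighted choice; p = 0 gives the
unweighted statistic, invariant to monotone score rescaling), non-members
subtract `1/(N - N_hit)`; ES is the signed maximum deviation. A
degenerate all-zero score vector falls back to the unweighted increment.
Significance comes from size-matched random gene sets
(`p = (1 + #{|ES_null| >= |ES_obs|}) / (n + 1)`, never below
`1/(n + 1)`); a per-sample phenotype permutation is meaningless when a
single prediction is being explained, which is why set resampling is the
null. NES divides ES by the mean |null ES| of matching sign. Both the
cell-feature column (cell-line SA-GSEA) and the drug columns
(target-importance reports) can be ranked.

## 7. The synthetic study

The generator emulates the six full-scale inputs at desk scale:

* a connected preferential-attachment network (confidences uniform on
  0.15–0.999, mimicking association score ranges);
* drugs with a fixed number of uniformly sampled targets and bundled
  small-molecule SMILES;
* dependency matrices (per-gene latent essentiality + cell noise, both
  standard-normal scale) and expression correlated with dependency at a
  configured level (default 0.6), with 5% of entries masked missing;
* synergy scores from a planted mechanism,
  `c1 * sum_g rA rB dep + c2 * (sum_g rA dep + sum_g rB dep)`
  (c1 = 1, c2 = 0.5), scaled so that 12.5% of noise-free records exceed
  the positive threshold 30 (keeping PR-AUC meaningful), plus Gaussian
  noise (sd 5 score units). The mechanism couples propagated profiles to
  dependency deliberately: recovering it tests exactly the modelling
  premise (network-propagated drug effect on essential genes drives
  synergy), not an arbitrary function;
* gene sets with one planted set (top genes of a designated signal
  vector) among random size-matched sets.

Default study conditions: 300 genes, 12 drugs (3 targets each), 8 cell
lines — 66 pairs × 8 cells = 528 records. The recovery experiments train
on one leave-combination fold (reduction 32, 4 heads, feed-forward 64,
head 64/32, dropout 0.1, learning rate 2e-3, 120 epochs; roughly 15 s on
one CPU) and reach held-out-pair Pearson well above 0.9 at the default
noise level. Attribution and enrichment checks reuse these sizes.

What passing these experiments does **not** show: real screens have
dose–response-derived synergy scores with heavy noise and batch
structure, drug-target annotations are incomplete and biased, real
interactome topology is denser and modular, and expression/dependency
have correlated gene blocks. The synthetic results validate the
machinery (shapes, math, protocols, recovery of a known mechanism), not
expected performance on any real screen.

## 8. Numerical choices and degenerate inputs

* Layer normalization epsilon 1e-5; softmax rows max-shifted before
  exponentiation.
* Transition-matrix column sums are validated at 1e-10; mass
  conservation at 1e-8.
* Zero-variance feature rows standardize to zero and are flagged rather
  than producing NaN; constant prediction sets get z = 0 by rule.
* Structured condition classes (`dsynet_*_error`) cover empty networks,
  targetless drugs, panel mismatches, unparseable SMILES, non-converged
  iterations, augmentation misuse, NaN training loss, and configuration
  errors (unknown keys are rejected with the offending name).
* Enrichment running sums accumulate via `cumsum` (extended precision);
  the brute-force oracle uses plain doubles, so equality is asserted at
  machine precision (1e-13), not bit identity.

## 9. Known limitations

* Training is pure R; it is comfortable at the package's study sizes and
  a few thousand records, but full-scale screens (tens of thousands of
  records on a 2401-gene panel) call for a GPU implementation.
* The GNF variant treats the graph-convolution stack as a fixed seeded
  featurizer rather than training it end-to-end with the main model.
* Imputation regresses on a capped number of complete rows; with very
  high missingness it degrades toward row means.
* Affinity propagation without jitter can oscillate on adversarially
  symmetric similarity matrices; the damping and convergence-window
  defaults handle realistic inputs.
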