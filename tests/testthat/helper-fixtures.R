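# Shared fixtures, built in code and cached for the duration of the run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, build(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Small synthetic study: 80 genes, 8 drugs, 5 cells.
tinyStudy <- function() cached("tinyStudy", function() {
  study <- simulateStudy(synthConfig(nGenes = 80L, nDrugs = 8L, nCells = 5L,
                                     targetsPerDrug = 2L, seed = 42L))
  study$depStd <- standardizeFeatures(imputeMissing(study$dependency))
  study$exprStd <- standardizeFeatures(imputeMissing(study$expression))
  study
})

tinyModelConfig <- function(panelSize = 80L, nTokens = 3L, seed = 7L,
                            epochs = 40L) {
  modelConfig(panelSize = panelSize, reducedDim = 16L, nHeads = 4L,
              nLayers = 1L, ffDim = 32L, dropout = 0.1,
              headHidden = c(32L, 16L), nTokens = nTokens, seed = seed,
              lr = 2e-3, batchSize = 32L, epochs = epochs)
}

# One trained model on the tiny study (leave-combination fold 1), reused by
# attribution and pipeline tests.
tinyTrainedFit <- function() cached("tinyTrainedFit", function() {
  study <- tinyStudy()
  plan <- splitLeaveCombinationOut(study$records, nFolds = 5L, seed = 1L)
  trainFold(study$records, plan@folds[[1]], study$profiles, study$depStd,
            config = tinyModelConfig(), evalEvery = 10L)
})

# Position-by-position brute-force enrichment running sum, independent of
# the streaming implementation.
bruteEs <- function(genes, scores, geneSet, p) {
  N <- length(genes)
  hits <- genes %in% geneSet
  wHit <- sum(abs(scores[hits])^p)
  rs <- numeric(N)
  run <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      run <- run + if (wHit == 0) 1 / sum(hits) else abs(scores[i])^p / wHit
    } else {
      run <- run - 1 / (N - sum(hits))
    }
    rs[i] <- run
  }
  rs[which.max(abs(rs))]
}

# Deterministic little record table for split tests.
toyRecords <- function(nDrugs = 5L, nCells = 2L, seed = 3L) {
  drugs <- sprintf("d%02d", seq_len(nDrugs))
  cells <- sprintf("c%d", seq_len(nCells))
  combos <- t(combn(drugs, 2L))
  set.seed(seed)
  do.call(rbind, lapply(cells, function(cl)
    data.frame(drugA = combos[, 1], drugB = combos[, 2], cell = cl,
               score = stats::rnorm(nrow(combos), 10, 25))))
}
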