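## Training, evaluation metrics and prioritization of untested pairs.

#' Build model input tensors for a set of synergy records
#'
#' @param records normalized record table (may carry a \code{swapped}
#'   column from \code{\link{augmentSwap}}; swapped rows get their drug
#'   columns in swapped order).
#' @param profiles a \code{\linkS4class{DrugProfileSet}}.
#' @param dependency,expression standardized
#'   \code{\linkS4class{CellFeatureMatrix}} objects (one or both).
#' @return list of \code{\linkS4class{SampleTensor}} in record order.
#' @export
buildSampleSet <- function(records, profiles, dependency = NULL,
                           expression = NULL) {
  lapply(seq_len(nrow(records)), function(i)
    assembleInput(records$drugA[i], records$drugB[i], records$cell[i],
                  profiles, dependency = dependency, expression = expression,
                  label = records$score[i]))
}

#' Regression and classification metrics for synergy prediction
#'
#' MSE, Pearson and Spearman correlation on the raw scores; ROC-AUC and
#' PR-AUC after binarizing the true scores at \code{threshold} (scores
#' strictly greater than the threshold are positives; the default 30 is
#' the established positive-synergy cutoff). PR-AUC uses trapezoidal
#' integration over distinct-score thresholds anchored at
#' (recall 0, precision 1); ROC-AUC comes from \pkg{pROC}.
#'
#' @param yTrue,yPred numeric vectors.
#' @param threshold classification boundary (default 30).
#' @return named list: \code{mse}, \code{pearson}, \code{spearman},
#'   \code{rocAuc}, \code{prAuc}, \code{threshold}, \code{nPositive}.
#' @export
computeMetrics <- function(yTrue, yPred, threshold = 30) {
  stopifnot(length(yTrue) == length(yPred))
  mse <- mean((yTrue - yPred)^2)
  pearson <- suppressWarnings(stats::cor(yTrue, yPred))
  spearman <- suppressWarnings(stats::cor(yTrue, yPred, method = "spearman"))
  labels <- yTrue > threshold
  rocAuc <- NA_real_; prAuc <- NA_real_
  if (length(unique(labels)) == 2L) {
    rocAuc <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = yPred, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
    prAuc <- prAucTrapezoid(labels, yPred)
  }
  list(mse = mse, pearson = pearson, spearman = spearman,
       rocAuc = rocAuc, prAuc = prAuc, threshold = threshold,
       nPositive = sum(labels))
}

## Trapezoidal precision-recall AUC over distinct prediction thresholds,
## anchored at (recall 0, precision 1).
prAucTrapezoid <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(lab)[keep]
  fp <- cumsum(!lab)[keep]
  P <- sum(lab)
  recall <- c(0, tp / P)
  precision <- c(1, tp / (tp + fp))
  sum(diff(recall) * (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
}

standardizeLabels <- function(y) {
  mu <- mean(y)
  sd <- stats::sd(y)
  if (!is.finite(sd) || sd == 0) sd <- 1
  list(center = mu, scale = sd, z = (y - mu) / sd)
}

#' Train a synergy model on one train/validation/test fold
#'
#' Minibatch Adam on the mean-squared error of label-standardized scores,
#' with pair-swap augmentation applied to the training portion only.
#' Validation MSE is monitored every \code{evalEvery} epochs and the
#' best-validation parameters are restored before test evaluation, so
#' epoch selection never sees the test fold. Metrics are computed on the
#' raw test records only (never on augmented rows).
#'
#' @param records normalized record table covering all ids in \code{fold}.
#' @param fold list with integer id vectors \code{train},
#'   \code{validation}, \code{test}.
#' @param profiles a \code{\linkS4class{DrugProfileSet}}.
#' @param dependency,expression standardized cell feature matrices.
#' @param config a \code{\link{modelConfig}}; \code{panelSize} and
#'   \code{nTokens} must match the assembled tensors.
#' @param augment apply pair-swap augmentation to the training records.
#' @param evalEvery validation cadence in epochs.
#' @param verbose print progress.
#' @return list: \code{model} (trained \code{SynergyModel}),
#'   \code{metrics} (test metrics), \code{history} (per-epoch training
#'   loss), \code{validationMse}.
#' @export
trainFold <- function(records, fold, profiles, dependency = NULL,
                      expression = NULL, config = modelConfig(),
                      augment = TRUE, evalEvery = 10L, verbose = FALSE) {
  records <- synergyRecords(records)
  trainRecs <- records[records$id %in% fold$train, ]
  valRecs <- records[records$id %in% fold$validation, ]
  testRecs <- records[records$id %in% fold$test, ]
  if (augment) trainRecs <- augmentSwap(markRole(trainRecs, "train"))
  trainSamples <- buildSampleSet(trainRecs, profiles, dependency, expression)
  valSamples <- buildSampleSet(valRecs, profiles, dependency, expression)
  model <- synergyModel(config)
  ls <- standardizeLabels(trainRecs$score)
  model@labelCenter <- ls$center
  model@labelScale <- ls$scale
  yTrain <- ls$z
  tokens <- tensorsToTokens(trainSamples)
  valTokens <- if (length(valSamples)) tensorsToTokens(valSamples) else NULL
  yVal <- if (length(valSamples)) valRecs$score else NULL
  n <- length(trainSamples)
  state <- adamInit(model@params)
  params <- model@params
  set.seed(config$seed)
  history <- numeric(0)
  bestVal <- Inf
  bestParams <- params
  valMse <- NA_real_
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / config$batchSize))
    epochLoss <- 0
    for (idx in batches) {
      bt <- lapply(tokens, function(T) T[idx, , drop = FALSE])
      fw <- nnForward(params, bt, config, training = TRUE)
      err <- fw$out - yTrain[idx]
      loss <- mean(err^2)
      if (!is.finite(loss))
        dsynetStop(sprintf("non-finite training loss at epoch %d", epoch),
                   "dsynet_training_error", epoch = epoch)
      bw <- nnBackward(params, fw$cache, 2 * err / length(idx), config)
      upd <- adamStep(params, bw$grads, state, lr = config$lr)
      params <- upd$params
      state <- upd$state
      epochLoss <- epochLoss + loss * length(idx)
    }
    history <- c(history, epochLoss / n)
    if (!is.null(valTokens) &&
        (epoch %% evalEvery == 0L || epoch == config$epochs)) {
      fwv <- nnForward(params, valTokens, config, training = FALSE)
      predVal <- fwv$out * model@labelScale + model@labelCenter
      valMse <- mean((predVal - yVal)^2)
      if (valMse < bestVal) {
        bestVal <- valMse
        bestParams <- params
      }
      if (verbose)
        message(sprintf("epoch %d: train %.4f, validation MSE %.2f",
                        epoch, utils::tail(history, 1), valMse))
    }
  }
  model@params <- if (is.finite(bestVal)) bestParams else params
  model@trained <- TRUE
  metrics <- NULL
  if (nrow(testRecs)) {
    testSamples <- buildSampleSet(testRecs, profiles, dependency, expression)
    pred <- predictSynergy(model, testSamples)
    metrics <- computeMetrics(testRecs$score, pred)
  }
  list(model = model, metrics = metrics, history = history,
       validationMse = if (is.finite(bestVal)) bestVal else valMse)
}

#' Train and evaluate a model across all folds of a split plan
#'
#' @param records normalized record table.
#' @param plan a \code{\linkS4class{SplitPlan}}.
#' @param profiles,dependency,expression model inputs (see
#'   \code{\link{trainFold}}).
#' @param config a \code{\link{modelConfig}}; the seed is offset per fold.
#' @param foldIndices optional subset of folds to run.
#' @param ... forwarded to \code{\link{trainFold}}.
#' @return list with \code{folds} (per-fold trainFold results) and
#'   \code{metrics} (one data.frame row per fold).
#' @export
trainSynergyModel <- function(records, plan, profiles, dependency = NULL,
                              expression = NULL, config = modelConfig(),
                              foldIndices = NULL, ...) {
  stopifnot(is(plan, "SplitPlan"))
  if (is.null(foldIndices)) foldIndices <- seq_along(plan@folds)
  results <- lapply(foldIndices, function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    trainFold(records, plan@folds[[i]], profiles, dependency, expression,
              config = cfg, ...)
  })
  mt <- do.call(rbind, lapply(seq_along(results), function(i) {
    m <- results[[i]]$metrics
    if (is.null(m)) return(NULL)
    data.frame(fold = foldIndices[i], mse = m$mse, pearson = m$pearson,
               spearman = m$spearman, rocAuc = m$rocAuc, prAuc = m$prAuc)
  }))
  list(folds = results, metrics = mt)
}

#' Rank novel drug pairs by per-cell-line z-score
#'
#' Synergy score distributions differ between cell lines, so predicted
#' scores are standardized within each cell line (population SD) before
#' global ranking: z = (score - mean_cell) / sd_cell. Cell lines where all
#' predictions are equal get z = 0; cell lines with a single prediction
#' have no defined z, are flagged and placed last. Ties are broken by
#' predicted score, then lexicographic ids.
#'
#' @param predictions data.frame with columns \code{drugA}, \code{drugB},
#'   \code{cell}, \code{score} (predicted).
#' @return the table sorted by z descending, with columns \code{z} and
#'   \code{zDefined}.
#' @export
rankNovelPairs <- function(predictions) {
  need <- c("drugA", "drugB", "cell", "score")
  if (!all(need %in% names(predictions)))
    dsynetStop("predictions need columns drugA, drugB, cell, score",
               "dsynet_input_error")
  tab <- as.data.frame(predictions)
  z <- rep(NA_real_, nrow(tab))
  for (cell in unique(tab$cell)) {
    idx <- which(tab$cell == cell)
    if (length(idx) < 2L) next
    s <- tab$score[idx]
    mu <- mean(s)
    sd <- sqrt(mean((s - mu)^2))   # population SD
    z[idx] <- if (sd == 0) 0 else (s - mu) / sd
  }
  tab$z <- z
  tab$zDefined <- !is.na(z)
  ord <- order(!tab$zDefined,            # undefined z last
               -ifelse(is.na(z), -Inf, z),
               -tab$score, tab$drugA, tab$drugB, tab$cell)
  out <- tab[ord, ]
  rownames(out) <- NULL
  out
}

#' Enumerate untested drug-pair/cell combinations and rank them
#'
#' Builds every unordered drug pair x cell-line combination absent from
#' the measured records, predicts their synergy with a trained model, and
#' returns the per-cell-line z-score ranking.
#'
#' @param model trained \code{\linkS4class{SynergyModel}}.
#' @param records measured record table (defines what is "tested").
#' @param profiles,dependency,expression model inputs.
#' @param cells cells to consider (default: those in the feature matrix).
#' @return ranked prediction table from \code{\link{rankNovelPairs}}.
#' @export
predictNovelPairs <- function(model, records, profiles, dependency = NULL,
                              expression = NULL, cells = NULL) {
  records <- synergyRecords(records)
  drugs <- drugIds(profiles)
  fm <- if (!is.null(dependency)) dependency else expression
  if (is.null(cells)) cells <- cellIds(fm)
  combos <- expand.grid(a = seq_along(drugs), b = seq_along(drugs),
                        cell = cells, stringsAsFactors = FALSE)
  combos <- combos[combos$a < combos$b, ]
  novel <- data.frame(drugA = drugs[combos$a], drugB = drugs[combos$b],
                      cell = combos$cell, score = NA_real_,
                      stringsAsFactors = FALSE)
  key <- function(a, b, cell)
    paste(ifelse(a < b, paste(a, b, sep = "+"), paste(b, a, sep = "+")),
          cell)
  tested <- key(records$drugA, records$drugB, records$cell)
  novel <- novel[!key(novel$drugA, novel$drugB, novel$cell) %in% tested, ]
  if (nrow(novel) == 0L) return(novel)
  samples <- buildSampleSet(novel, profiles, dependency, expression)
  novel$score <- predictSynergy(model, samples)
  rankNovelPairs(novel)
}
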