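## Cold-start evaluation protocols. Synergy records are rows of a plain
## data.frame (drugA, drugB, cell, score); a combination is an *unordered*
## drug pair, so (A, B, cell) and (B, A, cell) are the same measurement.
## Three splitting scenarios: leave-combination-out (pairs partitioned into
## folds), leave-cell-line-out and leave-drug-out (clusters from affinity
## propagation held out wholesale).

#' Validate and normalize a synergy record table
#'
#' @param records data.frame with columns \code{drugA}, \code{drugB},
#'   \code{cell}, \code{score}.
#' @return the table with character ids, a \code{pair} key column
#'   (lexicographically sorted drug ids) and a stable \code{id} column.
#' @export
synergyRecords <- function(records) {
  need <- c("drugA", "drugB", "cell", "score")
  if (!all(need %in% names(records)))
    dsynetStop("records need columns drugA, drugB, cell, score",
               "dsynet_input_error")
  records <- as.data.frame(records)[, need]
  for (col in c("drugA", "drugB", "cell"))
    records[[col]] <- as.character(records[[col]])
  if (any(records$drugA == records$drugB))
    dsynetStop("a drug cannot be combined with itself",
               "dsynet_input_error")
  records$pair <- ifelse(records$drugA < records$drugB,
                         paste(records$drugA, records$drugB, sep = "+"),
                         paste(records$drugB, records$drugA, sep = "+"))
  records$id <- seq_len(nrow(records))
  records
}

#' Read a synergy-score table (CSV: drug_a,drug_b,cell_line,synergy)
#' @param path file path; header required.
#' @return normalized record data.frame (see \code{\link{synergyRecords}}).
#' @export
readSynergyTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("drugA", "drugB", "cell", "score")
  synergyRecords(tab)
}

#' SplitPlan: train/validation/test partition for one evaluation scenario
#'
#' @slot scenario \code{"leave_combination"}, \code{"leave_cell"} or
#'   \code{"leave_drug"}.
#' @slot folds list; each element has integer record-id vectors
#'   \code{train}, \code{validation}, \code{test}.
#' @slot details scenario bookkeeping (cluster labels, held-out entities).
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(scenario = "character", folds = "list", details = "list"))

setValidity("SplitPlan", function(object) {
  if (!object@scenario %in% c("leave_combination", "leave_cell", "leave_drug"))
    return("unknown scenario")
  for (f in object@folds) {
    if (!all(c("train", "validation", "test") %in% names(f)))
      return("each fold needs train/validation/test ids")
    if (length(intersect(c(f$train, f$validation), f$test)))
      return("test records leak into training")
  }
  TRUE
})

#' @describeIn SplitPlan number of folds.
#' @param x,object a \code{SplitPlan}.
#' @export
setMethod("length", "SplitPlan", function(x) length(x@folds))

#' Fold accessor
#' @param x a \code{SplitPlan}.
#' @param i fold index.
#' @export
setGeneric("getFold", function(x, i) standardGeneric("getFold"))

#' @rdname getFold
#' @export
setMethod("getFold", "SplitPlan", function(x, i) x@folds[[i]])

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan (%s): %d fold(s)\n", object@scenario,
              length(object@folds)))
  for (i in seq_along(object@folds)) {
    f <- object@folds[[i]]
    cat(sprintf("  fold %d: %d train / %d validation / %d test\n", i,
                length(f$train), length(f$validation), length(f$test)))
  }
})

#' Leave-drug-combination-out cross-validation split
#'
#' Partitions the distinct unordered drug pairs into \code{nFolds}
#' near-equal groups (seeded shuffle); all records of a pair land in the
#' same fold. Nested structure: each fold serves as the test set once, one
#' of the remaining folds (rotating) is the validation set, the rest are
#' training.
#'
#' @param records normalized record table (\code{\link{synergyRecords}}).
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for the pair shuffle.
#' @return a \code{\linkS4class{SplitPlan}}.
#' @export
splitLeaveCombinationOut <- function(records, nFolds = 5L, seed = 1L) {
  records <- synergyRecords(records)
  pairs <- unique(records$pair)
  if (length(pairs) < nFolds)
    dsynetStop(sprintf("%d distinct pairs cannot fill %d folds",
                       length(pairs), nFolds), "dsynet_split_error")
  set.seed(seed)
  pairs <- sample(pairs)
  assignment <- rep(seq_len(nFolds), length.out = length(pairs))
  foldOfPair <- stats::setNames(assignment, pairs)
  folds <- lapply(seq_len(nFolds), function(tf) {
    vf <- tf %% nFolds + 1L   # rotate validation fold
    foldIdx <- foldOfPair[records$pair]
    list(train = records$id[!foldIdx %in% c(tf, vf)],
         validation = records$id[foldIdx == vf],
         test = records$id[foldIdx == tf])
  })
  new("SplitPlan", scenario = "leave_combination", folds = folds,
      details = list(foldOfPair = foldOfPair, nFolds = nFolds, seed = seed))
}

#' Pair-swap augmentation of a training set
#'
#' A combination's synergy cannot depend on which drug is called A and
#' which B, so the training set is doubled by adding every record with the
#' two drugs swapped, keeping the score. Must never be applied to
#' validation or test portions; pass the ids that constitute the training
#' fold via \code{trainIds} when the table carries a split.
#'
#' @param records normalized record table (training portion only).
#' @return record table of twice the rows; swapped copies carry
#'   \code{swapped = TRUE}.
#' @export
augmentSwap <- function(records) {
  role <- attr(records, "role")
  records <- synergyRecords(records)
  if (!is.null(role) && role != "train")
    dsynetStop("pair-swap augmentation is restricted to training data",
               "dsynet_augment_error")
  swapped <- records
  swapped$drugA <- records$drugB
  swapped$drugB <- records$drugA
  records$swapped <- FALSE
  swapped$swapped <- TRUE
  out <- rbind(records, swapped)
  rownames(out) <- NULL
  out
}

#' Mark a record table with its split role
#'
#' \code{\link{augmentSwap}} refuses tables marked as validation/test.
#' @param records record table.
#' @param role \code{"train"}, \code{"validation"} or \code{"test"}.
#' @export
markRole <- function(records, role = c("train", "validation", "test")) {
  role <- match.arg(role)
  attr(records, "role") <- role
  records
}

#' Affinity-propagation clustering
#'
#' Standard responsibility/availability message passing on the negative
#' squared Euclidean similarity, with the preference set to the median
#' off-diagonal similarity and damping 0.5. Deterministic given its
#' inputs (no jitter is added; exact ties in degenerate inputs are broken
#' by index order).
#'
#' @param features items x features numeric matrix.
#' @param preference exemplar preference; default median similarity.
#' @param damping damping factor in [0.5, 1).
#' @param maxIter maximum iterations.
#' @param convIter stop after this many iterations without label change.
#' @return integer cluster labels (1-based, contiguous), with exemplar
#'   indices in attribute \code{"exemplars"}.
#' @export
affinityPropagation <- function(features, preference = NULL, damping = 0.5,
                                maxIter = 500L, convIter = 50L) {
  X <- as.matrix(features)
  if (any(!is.finite(X)))
    dsynetStop("affinity propagation needs finite features",
               "dsynet_input_error")
  n <- nrow(X)
  if (n < 1L) dsynetStop("no items to cluster", "dsynet_input_error")
  if (n == 1L) return(structure(1L, exemplars = 1L))
  D2 <- as.matrix(stats::dist(X))^2
  S <- -D2
  if (is.null(preference))
    preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  lastLabels <- rep(0L, n)
  stable <- 0L
  for (it in seq_len(maxIter)) {
    ## responsibilities
    AS <- A + S
    idxMax <- max.col(AS, ties.method = "first")
    rowMax <- AS[cbind(seq_len(n), idxMax)]
    AStmp <- AS
    AStmp[cbind(seq_len(n), idxMax)] <- -Inf
    rowMax2 <- apply(AStmp, 1L, max)
    Rnew <- S - rowMax
    Rnew[cbind(seq_len(n), idxMax)] <- S[cbind(seq_len(n), idxMax)] - rowMax2
    R <- damping * R + (1 - damping) * Rnew
    ## availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colSumsRp <- colSums(Rp)
    Anew <- matrix(colSumsRp, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ## current exemplars/labels
    E <- diag(A) + diag(R) > 0
    exemplars <- which(E)
    if (length(exemplars) == 0L) exemplars <- which.max(diag(A) + diag(R))
    labels <- exemplars[max.col(S[, exemplars, drop = FALSE],
                                ties.method = "first")]
    labels[exemplars] <- exemplars
    if (identical(labels, lastLabels)) stable <- stable + 1L else stable <- 0L
    lastLabels <- labels
    if (stable >= convIter) break
  }
  if (stable < convIter)
    dsynetStop(sprintf("affinity propagation did not converge in %d iterations",
                       maxIter), "dsynet_convergence_error",
               iterations = maxIter)
  out <- match(lastLabels, sort(unique(lastLabels)))
  structure(as.integer(out), exemplars = sort(unique(lastLabels)))
}

#' Leave-cell-line-out split
#'
#' Cell lines are clustered by affinity propagation on their feature
#' vectors; the largest cluster becomes the training/validation pool and
#' every other cell line is held out as test, so test cells are maximally
#' dissimilar from training cells.
#'
#' @param records normalized record table.
#' @param cellFeatures cells x features matrix (rownames = cell ids), e.g.
#'   the transpose of a standardized \code{\linkS4class{CellFeatureMatrix}}.
#' @param validationFraction fraction of training *cells* set aside for
#'   validation (seeded).
#' @param seed integer seed.
#' @return a single-fold \code{\linkS4class{SplitPlan}}; cluster labels in
#'   \code{details}.
#' @export
splitLeaveCellOut <- function(records, cellFeatures, validationFraction = 0.2,
                              seed = 1L) {
  records <- synergyRecords(records)
  cells <- rownames(cellFeatures)
  if (is.null(cells))
    dsynetStop("cellFeatures needs cell-line rownames", "dsynet_input_error")
  missing <- setdiff(unique(records$cell), cells)
  if (length(missing))
    dsynetStop(paste("cells without features:",
                     paste(utils::head(missing, 5), collapse = ", ")),
               "dsynet_input_error")
  labels <- affinityPropagation(cellFeatures)
  sizes <- table(labels)
  big <- as.integer(names(sizes)[which.max(sizes)])
  trainCells <- cells[labels == big]
  testCells <- setdiff(cells, trainCells)
  set.seed(seed)
  nVal <- max(1L, round(validationFraction * length(trainCells)))
  valCells <- sample(trainCells, min(nVal, length(trainCells) - 1L))
  fitCells <- setdiff(trainCells, valCells)
  folds <- list(list(train = records$id[records$cell %in% fitCells],
                     validation = records$id[records$cell %in% valCells],
                     test = records$id[records$cell %in% testCells]))
  new("SplitPlan", scenario = "leave_cell", folds = folds,
      details = list(clusters = stats::setNames(labels, cells),
                     trainCells = trainCells, testCells = testCells))
}

#' Leave-drug-out split
#'
#' Drugs are clustered by affinity propagation on structural fingerprints.
#' Each of the \code{nHoldout} smallest clusters is held out in turn:
#' every record whose pair contains any held-out drug goes to test (even
#' when the partner is a training drug), the remaining records form the
#' training/validation pool (validation = seeded fraction of training
#' pairs). Holding out small clusters keeps train:test near 4:1.
#'
#' @param records normalized record table.
#' @param drugFingerprints drugs x features matrix (rownames = drug ids).
#' @param nHoldout how many of the smallest clusters to hold out in turn
#'   (default 3).
#' @param validationFraction fraction of training pairs for validation.
#' @param seed integer seed.
#' @return a \code{\linkS4class{SplitPlan}} with one fold per held-out
#'   cluster.
#' @export
splitLeaveDrugOut <- function(records, drugFingerprints, nHoldout = 3L,
                              validationFraction = 0.2, seed = 1L) {
  records <- synergyRecords(records)
  drugs <- rownames(drugFingerprints)
  if (is.null(drugs))
    dsynetStop("drugFingerprints needs drug rownames", "dsynet_input_error")
  missing <- setdiff(unique(c(records$drugA, records$drugB)), drugs)
  if (length(missing))
    dsynetStop(paste("drugs without fingerprints:",
                     paste(utils::head(missing, 5), collapse = ", ")),
               "dsynet_input_error")
  labels <- affinityPropagation(drugFingerprints)
  sizes <- sort(table(labels))
  heldClusters <- as.integer(names(sizes))[seq_len(min(nHoldout, length(sizes)))]
  folds <- lapply(heldClusters, function(cl) {
    heldDrugs <- drugs[labels == cl]
    inTest <- records$drugA %in% heldDrugs | records$drugB %in% heldDrugs
    rest <- records[!inTest, ]
    set.seed(seed + cl)
    pairs <- unique(rest$pair)
    valPairs <- sample(pairs, max(1L, round(validationFraction * length(pairs))))
    list(train = rest$id[!rest$pair %in% valPairs],
         validation = rest$id[rest$pair %in% valPairs],
         test = records$id[inTest])
  })
  new("SplitPlan", scenario = "leave_drug", folds = folds,
      details = list(clusters = stats::setNames(labels, drugs),
                     heldClusters = heldClusters))
}

#' Export / import a split plan as JSON for exact reruns
#' @param plan a \code{\linkS4class{SplitPlan}}.
#' @param path JSON file path.
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(list(scenario = plan@scenario,
                            folds = lapply(plan@folds, lapply, as.integer)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(x$folds, function(f)
    lapply(f, function(ids) as.integer(unlist(ids))))
  new("SplitPlan", scenario = x$scenario, folds = folds, details = list())
}
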