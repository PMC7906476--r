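# Evaluation protocols: splits, augmentation, clustering, metrics,
# z-score ranking.

test_that("leave-combination folds partition unordered pairs", {
  recs <- toyRecords(nDrugs = 5L, nCells = 2L)     # 10 pairs x 2 cells
  plan <- splitLeaveCombinationOut(recs, nFolds = 5L, seed = 2L)
  expect_equal(length(plan), 5L)
  expect_identical(eval(formals(splitLeaveCombinationOut)$nFolds), 5L)
  norm <- synergyRecords(recs)
  # 10 pairs over 5 folds: exactly 2 pairs per fold, records follow pairs
  foldPairs <- lapply(plan@folds, function(f)
    unique(norm$pair[norm$id %in% f$test]))
  expect_true(all(lengths(foldPairs) == 2L))
  expect_equal(sort(unlist(foldPairs)), sort(unique(norm$pair)))
  # no pair ever appears on both sides of a fold
  for (f in plan@folds) {
    trainPairs <- norm$pair[norm$id %in% c(f$train, f$validation)]
    testPairs <- norm$pair[norm$id %in% f$test]
    expect_length(intersect(trainPairs, testPairs), 0L)
  }
  expect_error(splitLeaveCombinationOut(recs[1:3, ], nFolds = 5L),
               class = "dsynet_split_error")
})

test_that("records of a pair share a fold regardless of drug order", {
  recs <- data.frame(drugA = c("A", "B", "A", "C", "C", "B"),
                     drugB = c("B", "A", "C", "A", "B", "C"),
                     cell = c("c1", "c2", "c1", "c2", "c1", "c2"),
                     score = 1:6)
  plan <- splitLeaveCombinationOut(recs, nFolds = 3L, seed = 1L)
  norm <- synergyRecords(recs)
  for (f in plan@folds) {
    testPairs <- norm$pair[norm$id %in% f$test]
    # every record of a test pair is in the test set
    expect_setequal(f$test, norm$id[norm$pair %in% testPairs])
  }
})

test_that("pair-swap augmentation doubles training data and keeps labels", {
  recs <- toyRecords()[1:3, ]
  aug <- augmentSwap(recs)
  expect_equal(nrow(aug), 6L)
  expect_equal(aug$score[4:6], recs$score)
  expect_equal(aug$drugA[4:6], recs$drugB)
  expect_equal(aug$drugB[4:6], recs$drugA)
  # swap is an involution on unordered pairs: nothing new appears
  expect_setequal(unique(aug$pair), unique(synergyRecords(recs)$pair))
  # refusing non-training portions
  expect_error(augmentSwap(markRole(recs, "test")),
               class = "dsynet_augment_error")
})

test_that("affinity propagation separates well-separated blobs", {
  set.seed(8)
  X <- rbind(matrix(rnorm(10, mean = 0, sd = 0.05), 5, 2),
             matrix(rnorm(10, mean = 5, sd = 0.05), 5, 2))
  labels <- affinityPropagation(X)
  expect_equal(length(unique(labels)), 2L)
  expect_equal(length(unique(labels[1:5])), 1L)
  expect_equal(length(unique(labels[6:10])), 1L)
  expect_false(labels[1] == labels[6])
  # the chosen exemplars maximise within-cluster similarity versus any
  # other single-exemplar choice inside each blob (brute-force audit)
  S <- -as.matrix(dist(X))^2
  ex <- attr(labels, "exemplars")
  netSim <- sum(S[cbind(seq_len(10), ex[labels])])
  for (e1 in 1:5) for (e2 in 6:10) {
    alt <- ifelse(seq_len(10) <= 5, e1, e2)
    expect_lte(sum(S[cbind(seq_len(10), alt)]), netSim + 1e-9)
  }

  # a duplicated item always joins its twin's cluster
  Xd <- rbind(X, X[1, ])
  ld <- affinityPropagation(Xd)
  expect_equal(ld[11], ld[1])

  # degenerate single item
  expect_equal(as.integer(affinityPropagation(matrix(1, 1, 2))), 1L)
})

test_that("leave-cell-out holds out everything but the largest cluster", {
  set.seed(3)
  cells <- sprintf("cl%d", 1:7)
  feats <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
                 matrix(rnorm(6, 6, 0.1), 3, 2))
  rownames(feats) <- cells
  drugs <- sprintf("d%d", 1:4)
  combos <- t(combn(drugs, 2))
  recs <- do.call(rbind, lapply(cells, function(cl)
    data.frame(drugA = combos[, 1], drugB = combos[, 2], cell = cl,
               score = rnorm(nrow(combos)))))
  plan <- splitLeaveCellOut(recs, feats, seed = 4L)
  norm <- synergyRecords(recs)
  f <- plan@folds[[1]]
  trainCells <- unique(norm$cell[norm$id %in% c(f$train, f$validation)])
  testCells <- unique(norm$cell[norm$id %in% f$test])
  expect_length(intersect(trainCells, testCells), 0L)
  expect_setequal(trainCells, cells[1:4])     # the dominant cluster
  expect_setequal(testCells, cells[5:7])
})

test_that("leave-drug-out sends every pair touching a held-out drug to test", {
  set.seed(6)
  nDrugs <- 15L
  drugs <- sprintf("d%02d", seq_len(nDrugs))
  # three structural families of different sizes
  fam <- rep(1:3, c(8, 4, 3))
  fp <- matrix(rnorm(nDrugs * 4, mean = fam * 4, sd = 0.2), nDrugs, 4)
  rownames(fp) <- drugs
  combos <- t(combn(drugs, 2))
  recs <- data.frame(drugA = combos[, 1], drugB = combos[, 2],
                     cell = "c1", score = rnorm(nrow(combos)))
  plan <- splitLeaveDrugOut(recs, fp, nHoldout = 2L, seed = 1L)
  norm <- synergyRecords(recs)
  expect_equal(length(plan), 2L)
  for (i in seq_along(plan@folds)) {
    f <- plan@folds[[i]]
    held <- names(plan@details$clusters)[
      plan@details$clusters == plan@details$heldClusters[i]]
    touches <- norm$drugA %in% held | norm$drugB %in% held
    # exhaustive audit: test = exactly the records touching held drugs
    expect_setequal(f$test, norm$id[touches])
    trainDrugs <- unique(c(norm$drugA[norm$id %in% f$train],
                           norm$drugB[norm$id %in% f$train]))
    expect_length(intersect(trainDrugs, held), 0L)
    # a pair with one held-out drug is in test even if the partner trains
    mixed <- norm$id[(norm$drugA %in% held) != (norm$drugB %in% held)]
    expect_true(all(mixed %in% f$test))
  }
})

test_that("metrics match brute-force oracles", {
  # identity prediction
  m <- computeMetrics(c(1, 5, 40), c(1, 5, 40))
  expect_equal(m$mse, 0)
  expect_equal(m$pearson, 1)
  expect_equal(m$spearman, 1)
  # default binarization boundary is 30
  expect_equal(m$threshold, 30)
  expect_equal(m$nPositive, 1L)
  expect_identical(eval(formals(computeMetrics)$threshold), 30)

  # two points, one positive: perfect ranking gives ROC-AUC 1
  m2 <- computeMetrics(c(10, 40), c(0.1, 0.9))
  expect_equal(m2$rocAuc, 1)

  # brute-force comparison on random vectors
  bruteRoc <- function(lab, sc) {
    pos <- sc[lab]; neg <- sc[!lab]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  brutePr <- function(lab, sc) {
    ths <- sort(unique(sc), decreasing = TRUE)
    rec <- c(0, vapply(ths, function(t) sum(lab & sc >= t) / sum(lab), 0))
    prec <- c(1, vapply(ths, function(t) sum(lab & sc >= t) / sum(sc >= t), 0))
    sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  }
  bruteSpearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  set.seed(14)
  for (i in 1:100) {
    y <- rnorm(25, 20, 20)
    p <- y * runif(1, 0.5, 2) + rnorm(25, sd = 10)
    if (length(unique(y > 30)) < 2) next
    m <- computeMetrics(y, p)
    lab <- y > 30
    expect_equal(m$rocAuc, bruteRoc(lab, p), tolerance = 1e-10)
    expect_equal(m$prAuc, brutePr(lab, p), tolerance = 1e-10)
    expect_equal(m$spearman, bruteSpearman(y, p), tolerance = 1e-10)
    expect_equal(m$mse, sum((y - p)^2) / 25, tolerance = 1e-12)
  }
})

test_that("novel pairs are ranked by per-cell-line population z-score", {
  tab <- data.frame(drugA = c("a", "a", "b", "x", "x", "y"),
                    drugB = c("b", "c", "c", "y", "z", "z"),
                    cell = c("c1", "c1", "c1", "c2", "c2", "c2"),
                    score = c(1, 2, 3, 7, 7, 7))
  out <- rankNovelPairs(tab)
  # z of (1,2,3) is (-1.2247, 0, 1.2247); constant cell gets all zeros
  z1 <- out$z[out$cell == "c1"]
  expect_equal(sort(z1), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_true(all(out$z[out$cell == "c2"] == 0))
  # sorted by z descending
  expect_true(all(diff(out$z) <= 1e-12))

  # single-prediction cell line: undefined z, flagged, placed last
  tab2 <- rbind(tab, data.frame(drugA = "q", drugB = "r", cell = "c3",
                                score = 100))
  out2 <- rankNovelPairs(tab2)
  expect_false(out2$zDefined[nrow(out2)])
  expect_equal(out2$cell[nrow(out2)], "c3")
})

test_that("split plans survive a JSON round trip", {
  recs <- toyRecords()
  plan <- splitLeaveCombinationOut(recs, seed = 9L)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "plan.json")
  writeSplitPlan(plan, f)
  back <- readSplitPlan(f)
  expect_equal(back@scenario, plan@scenario)
  for (i in seq_along(plan@folds))
    for (part in c("train", "validation", "test"))
      expect_equal(back@folds[[i]][[part]], plan@folds[[i]][[part]])
})
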