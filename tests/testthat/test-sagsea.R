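# Attribution-driven gene set enrichment: expected gradients, ranked
# lists, weighted KS statistic, permutation significance.

test_that("linear models have closed-form expected-gradients attributions", {
  set.seed(2)
  w <- matrix(rnorm(12), 4, 3)
  valueGrad <- function(inputs)
    list(values = vapply(inputs, function(x) sum(w * x), 0),
         grads = lapply(inputs, function(x) w))
  x <- matrix(rnorm(12), 4, 3)
  b <- matrix(rnorm(12), 4, 3)
  attr <- dsynet:::expectedGradients(valueGrad, x, list(b), steps = 4L,
                                     nRepeats = 1L, seed = 1L)
  expect_equal(attr, w * (x - b), tolerance = 1e-12)  # exact for linear f
  # additivity is exact too: sum = f(x) - f(b)
  expect_equal(sum(attr), sum(w * x) - sum(w * b), tolerance = 1e-10)
})

test_that("attributions on a trained model satisfy additivity", {
  fit <- tinyTrainedFit()
  study <- tinyStudy()
  recs <- synergyRecords(study$records)
  samples <- buildSampleSet(recs, study$profiles, study$depStd)
  bg <- backgroundCentroids(samples, k = 10L, seed = 3L)
  idx <- which.max(abs(recs$score))
  rep <- computeAttributions(fit$model, samples[[idx]], bg,
                             attributionConfig(nRepeats = 3L,
                                               integrationSteps = 128L,
                                               seed = 5L))
  total <- sum(attributions(rep))
  target <- rep@modelOutput - rep@backgroundExpectation
  expect_lt(abs(total - target) / max(abs(target), 1e-8), 0.05)
  # untrained models are refused
  expect_error(computeAttributions(synergyModel(tinyModelConfig()),
                                   samples[[1]], bg),
               class = "dsynet_model_error")
})

test_that("more repeats reduce attribution variance", {
  fit <- tinyTrainedFit()
  study <- tinyStudy()
  samples <- buildSampleSet(synergyRecords(study$records)[1:20, ],
                            study$profiles, study$depStd)
  bg <- backgroundCentroids(samples, k = 4L, seed = 3L)
  s <- samples[[1]]
  est <- function(nRepeats, seed) {
    sum(attributions(computeAttributions(
      fit$model, s, bg, attributionConfig(nRepeats = nRepeats,
                                          integrationSteps = 4L,
                                          seed = seed)))[, 3])
  }
  v1 <- var(vapply(1:20, function(s_) est(1L, s_), 0))
  v4 <- var(vapply(1:20, function(s_) est(4L, s_), 0))
  expect_lt(v4, v1)
})

test_that("gene ranking follows attribution with declared tie-breaks", {
  A <- matrix(c(0.5, -0.1, 0.5), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "cell_dependency"))
  rep <- new("AttributionReport", attributions = A, modelOutput = 1,
             backgroundExpectation = 0, config = list())
  r <- rankGenes(rep, "cell_dependency")
  expect_equal(r$gene, c("g1", "g3", "g2"))   # tie broken lexicographically

  # all-zero attributions: alphabetical, zero scores
  A0 <- A; A0[] <- 0
  rep0 <- new("AttributionReport", attributions = A0, modelOutput = 0,
              backgroundExpectation = 0, config = list())
  r0 <- rankGenes(rep0, "cell_dependency")
  expect_equal(r0$gene, c("g1", "g2", "g3"))
  expect_true(all(r0$score == 0))

  # negation reverses the order of non-tied genes
  An <- matrix(c(3, 1, 2), 3, 1,
               dimnames = list(c("g1", "g2", "g3"), "cell_dependency"))
  repP <- new("AttributionReport", attributions = An, modelOutput = 0,
              backgroundExpectation = 0, config = list())
  repN <- new("AttributionReport", attributions = -An, modelOutput = 0,
              backgroundExpectation = 0, config = list())
  expect_equal(rankGenes(repP, "cell_dependency")$gene,
               rev(rankGenes(repN, "cell_dependency")$gene))
})

test_that("enrichment scores match the brute-force running sum exactly", {
  # top-ranked singleton with p = 0 peaks at 1 after the first position
  ranked <- data.frame(gene = paste0("g", 1:6), score = c(6:1))
  expect_equal(enrichmentScore(ranked, "g1", weightP = 0)$es, 1)

  # five genes, scores 5..1, set = two top genes, p = 1:
  # running sum reaches (5+4)/9 ... climbing to 1.0 at position 2
  r5 <- data.frame(gene = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  es <- enrichmentScore(r5, c("g1", "g2"), weightP = 1)
  expect_equal(es$es, 1.0)
  expect_equal(es$runningSum[1], 5 / 9)

  # bottom-ranked singleton: all misses first, deepest at position N-1
  esB <- enrichmentScore(ranked, "g6", weightP = 0)
  expect_equal(esB$es, bruteEs(ranked$gene, ranked$score, "g6", 0))
  expect_equal(min(esB$runningSum), esB$es)

  # random cases, N <= 20: streaming equals brute force exactly
  set.seed(31)
  for (i in 1:50) {
    N <- sample(5:20, 1)
    genes <- paste0("g", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(genes, sample(1:(N - 1), 1))
    p <- sample(c(0, 1, 2), 1)
    rk <- data.frame(gene = genes, score = scores)
    # agreement to machine precision (the streaming path accumulates in
    # extended precision via cumsum, the oracle in plain doubles)
    expect_equal(enrichmentScore(rk, set, p)$es,
                 bruteEs(genes, scores, set, p), tolerance = 1e-13)
    expect_lte(abs(enrichmentScore(rk, set, p)$es), 1)
  }

  # degenerate sets are structured errors
  expect_error(enrichmentScore(ranked, "absent"),
               class = "dsynet_enrichment_error")
  expect_error(enrichmentScore(ranked, ranked$gene),
               class = "dsynet_enrichment_error")
})

test_that("unweighted enrichment is invariant to monotone score rescaling", {
  set.seed(7)
  genes <- paste0("g", 1:15)
  scores <- sort(rnorm(15), decreasing = TRUE)
  set <- sample(genes, 4)
  rk1 <- data.frame(gene = genes, score = scores)
  rk2 <- data.frame(gene = genes, score = scores * 100 + 3)
  expect_identical(enrichmentScore(rk1, set, weightP = 0)$es,
                   enrichmentScore(rk2, set, weightP = 0)$es)
})

test_that("enrichment scores agree with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(12)
  genes <- paste0("g", 1:40)
  scores <- sort(rexp(40), decreasing = TRUE)   # positive, so |s|^1 = s
  rk <- data.frame(gene = genes, score = scores)
  for (i in 1:10) {
    set <- sample(genes, 8)
    mine <- enrichmentScore(rk, set, weightP = 1)$es
    stats <- stats::setNames(scores, genes)
    ref <- fgsea::calcGseaStat(stats, selectedStats = match(set, genes),
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values behave like p-values", {
  set.seed(9)
  genes <- paste0("g", 1:30)
  rk <- data.frame(gene = genes, score = sort(rnorm(30), decreasing = TRUE))
  res <- permutationSignificance(rk, sample(genes, 6), nPermutations = 199L,
                                 seed = 2L)
  expect_gte(res$p, 1 / 200)
  expect_lte(res$p, 1)
  expect_error(permutationSignificance(rk, genes[1:3], nPermutations = 10L),
               class = "dsynet_config_error")

  # null uniformity: random sets under random scores over many reruns
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    scores <- sort(rnorm(30), decreasing = TRUE)
    rki <- data.frame(gene = genes, score = scores)
    permutationSignificance(rki, sample(genes, 5), nPermutations = 199L,
                            seed = i)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # a set planted at the top of the ranking is significant
  planted <- genes[1:5]
  rkTop <- data.frame(gene = genes, score = sort(rexp(30), decreasing = TRUE))
  resP <- permutationSignificance(rkTop, planted, nPermutations = 1000L,
                                  seed = 3L)
  expect_lte(resP$p, 0.01)
  expect_gt(resP$nes, 1)
})

test_that("GMT files round-trip bit-identically", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  attr(sets, "descriptions") <- c(alpha = "first", beta = "second")
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sets.gmt")
  writeGMT(sets, f)
  back <- readGMT(f)
  expect_identical(back$alpha, sets$alpha)
  expect_identical(back$beta, sets$beta)
  expect_identical(attr(back, "descriptions"), attr(sets, "descriptions"))
  writeGMT(back, file.path(dir, "sets2.gmt"))
  expect_identical(readLines(f), readLines(file.path(dir, "sets2.gmt")))
  writeLines("broken\tonly-two-fields", file.path(dir, "bad.gmt"))
  expect_error(readGMT(file.path(dir, "bad.gmt")),
               class = "dsynet_input_error")
})

test_that("saGsea surfaces the planted set first on a planted ranking", {
  study <- tinyStudy()
  # rank genes by the generator's planted signal itself
  signal <- colSums(propagatedProfiles(study$profiles)) *
    rowMeans(abs(study$latentDependency))
  A <- matrix(sort(signal, decreasing = TRUE), ncol = 1,
              dimnames = list(names(sort(signal, decreasing = TRUE)),
                              "cell_dependency"))
  rep <- new("AttributionReport", attributions = A[order(rownames(A)), ,
                                                   drop = FALSE],
             modelOutput = 1, backgroundExpectation = 0, config = list())
  res <- saGsea(rep, study$geneSets, nPermutations = 200L, seed = 1L)
  expect_equal(res$geneSet[1], "planted_top")
  expect_lte(res$p[1], 0.05)
})
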