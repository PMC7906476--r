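# Network construction and random-walk-with-restart propagation.

test_that("transition matrix normalizes columns as hand-computed", {
  # one edge: both columns are unit vectors toward the other node
  W1 <- buildTransitionMatrix(
    geneNetwork(data.frame(geneA = "a", geneB = "b", confidence = 0.9)))
  expect_equal(unname(as.matrix(W1@W)), matrix(c(0, 1, 1, 0), 2))

  # path a-b (w=1), b-c (w=3): column b splits 1/4 vs 3/4
  W2 <- buildTransitionMatrix(
    geneNetwork(data.frame(geneA = c("a", "b"), geneB = c("b", "c"),
                           confidence = c(1, 3))))
  expect_equal(as.numeric(W2@W[, "b"]), c(0.25, 0, 0.75))
  expect_true(all(abs(Matrix::colSums(W2@W) - 1) < 1e-10))

  # isolated node: self-loop column under the default policy
  W3 <- buildTransitionMatrix(
    geneNetwork(data.frame(geneA = "a", geneB = "b", confidence = 1),
                geneIds = c("a", "b", "z")))
  expect_equal(as.numeric(W3@W[, "z"]), c(0, 0, 1))
  # teleport policy leaves the dangling column empty instead
  W4 <- buildTransitionMatrix(
    geneNetwork(data.frame(geneA = "a", geneB = "b", confidence = 1),
                geneIds = c("a", "b", "z")), danglingPolicy = "teleport")
  expect_equal(sum(W4@W[, "z"]), 0)
})

test_that("invalid networks raise structured errors", {
  expect_error(geneNetwork(data.frame(geneA = character(),
                                      geneB = character(),
                                      confidence = numeric())),
               class = "dsynet_empty_network")
  expect_error(geneNetwork(data.frame(geneA = "a", geneB = "b",
                                      confidence = -1)),
               class = "dsynet_input_error")
})

test_that("random walk with restart matches hand-derived solutions", {
  W <- buildTransitionMatrix(
    geneNetwork(data.frame(geneA = "a", geneB = "b", confidence = 1)))
  # alpha = 0 forces r = e
  expect_equal(unname(rwrPropagate(W, c(0, 1), propagationConfig(alpha = 0))),
               c(0, 1))
  # (I - 0.5 W) r = 0.5 e with W = [[0,1],[1,0]], e = (1,0): r = (2/3, 1/3)
  r <- rwrPropagate(W, c(1, 0), propagationConfig(alpha = 0.5))
  expect_equal(unname(r), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # walk-on probability defaults to the validation-selected 0.5
  expect_equal(propagationConfig()$alpha, 0.5)
})

test_that("direct and power solvers agree and conserve mass", {
  set.seed(11)
  n <- 50L
  ids <- sprintf("g%02d", 1:n)
  edges <- data.frame(geneA = ids[sample(n, 150, TRUE)],
                      geneB = ids[sample(n, 150, TRUE)],
                      confidence = runif(150, 0.2, 1))
  edges <- edges[edges$geneA != edges$geneB, ]
  net <- geneNetwork(edges, geneIds = ids)
  W <- buildTransitionMatrix(net)
  seed <- as.numeric(seq_len(n) %in% c(3, 17))
  for (alpha in c(0.1, 0.5, 0.9)) {
    rd <- rwrPropagate(W, seed, propagationConfig(alpha = alpha, solver = "direct"))
    rp <- rwrPropagate(W, seed, propagationConfig(alpha = alpha, solver = "power",
                                                  tol = 1e-10, maxIter = 5000))
    expect_lt(max(abs(rd - rp)), 1e-6)
    expect_equal(sum(rd), 1, tolerance = 1e-8)  # mass conservation
  }
})

test_that("propagation matches an independent dense linear solve", {
  study <- simulateStudy(synthConfig(nGenes = 100L, nDrugs = 4L,
                                     nCells = 3L, seed = 5L))
  W <- buildTransitionMatrix(study$network)
  Wd <- as.matrix(W@W)
  n <- nrow(Wd)
  seed <- as.numeric(seq_len(n) %in% c(1, 10, 55))
  e <- seed / sum(seed)
  for (alpha in seq(0, 0.9, by = 0.1)) {
    r <- rwrPropagate(W, seed, propagationConfig(alpha = alpha))
    oracle <- base::solve(diag(n) - alpha * Wd, (1 - alpha) * e)
    expect_lt(max(abs(r - oracle)), 1e-8)
    # fixed-point residual: r = alpha W r + (1-alpha) e
    expect_lt(max(abs(alpha * Wd %*% r + (1 - alpha) * e - r)), 1e-8)
  }
})

test_that("propagated mass concentrates on and around the targets", {
  study <- simulateStudy(synthConfig(nGenes = 120L, nDrugs = 4L,
                                     nCells = 3L, seed = 9L))
  W <- buildTransitionMatrix(study$network)
  n <- length(geneIds(study$network))
  set.seed(21)
  for (alpha in c(0.1, 0.3, 0.5)) {
    seedGenes <- sample(n, 3L)
    seed <- as.numeric(seq_len(n) %in% seedGenes)
    r <- rwrPropagate(W, seed, propagationConfig(alpha = alpha))
    seedMass <- sum(r[seedGenes])
    for (rep in 1:20) {
      other <- sample(setdiff(seq_len(n), seedGenes), 3L)
      expect_gte(seedMass, sum(r[other]))
    }
  }
})

test_that("power solver reports non-convergence as a structured error", {
  W <- buildTransitionMatrix(
    geneNetwork(data.frame(geneA = "a", geneB = "b", confidence = 1)))
  expect_error(
    rwrPropagate(W, c(1, 0), propagationConfig(alpha = 0.9, solver = "power",
                                               tol = 1e-14, maxIter = 2L)),
    class = "dsynet_convergence_error")
})

test_that("propagateDrugs keeps mapped drugs and reports rejects", {
  net <- geneNetwork(data.frame(geneA = c("a", "b"), geneB = c("b", "c"),
                                confidence = c(1, 1)))
  targets <- data.frame(drug = c("d1", "d1", "d2", "d3"),
                        gene = c("a", "b", "c", "zz"))
  profiles <- propagateDrugs(net, targets)
  expect_setequal(drugIds(profiles), c("d1", "d2"))
  expect_true("d3" %in% profiles@rejects)
  expect_true("zz" %in% attr(profiles@rejects, "droppedTargets"))
  expect_equal(unname(rowSums(propagatedProfiles(profiles))),
               rep(1, 2), tolerance = 1e-8)
  # seeds must be binary with at least one target
  expect_error(rwrPropagate(buildTransitionMatrix(net), c(0, 0, 0)),
               class = "dsynet_empty_seed")
})

test_that("edge list and profile writers round-trip", {
  dir <- withr::local_tempdir()
  edges <- data.frame(geneA = c("a", "b"), geneB = c("b", "c"),
                      confidence = c(0.4, 0.8))
  f <- file.path(dir, "edges.tsv")
  write.table(edges, f, sep = "\t", quote = FALSE, row.names = FALSE)
  net <- readEdgeList(f)
  expect_equal(sort(geneIds(net)), c("a", "b", "c"))
  # headerless, whitespace-delimited dialect
  f2 <- file.path(dir, "edges.txt")
  writeLines(c("a b 0.4", "b c 0.8"), f2)
  net2 <- readEdgeList(f2)
  expect_equal(net2@edges$confidence, net@edges$confidence)

  profiles <- propagateDrugs(net, data.frame(drug = "d1", gene = "a"))
  out <- file.path(dir, "profiles.tsv")
  writeProfiles(profiles, out)
  back <- read.table(out, header = TRUE, sep = "\t", row.names = 1)
  expect_equal(colnames(back), geneIds(net))
  expect_equal(as.numeric(back["d1", ]),
               unname(propagatedProfiles(profiles)["d1", ]),
               tolerance = 1e-9)
})
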