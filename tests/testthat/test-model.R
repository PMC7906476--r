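# Transformer regression model: attention algebra, reduction, forward
# pass, gradients, optimization behaviour.

test_that("scaled dot-product attention matches hand arithmetic", {
  # one token: softmax over a single element is 1, output is V exactly
  out1 <- scaledDotAttention(matrix(2.3), matrix(-1), matrix(7.7))
  expect_identical(out1$output, matrix(7.7))
  expect_identical(out1$weights, matrix(1))

  # two tokens, d = 1, Q = K = (1, 0), V = (1, 3)
  res <- scaledDotAttention(matrix(c(1, 0)), matrix(c(1, 0)),
                            matrix(c(1, 3)))
  w1 <- exp(1) / (exp(1) + 1)           # softmax([1, 0]) by hand
  expect_equal(res$weights[1, ], c(w1, 1 - w1), tolerance = 1e-6)
  expect_equal(res$output[1, 1], w1 * 1 + (1 - w1) * 3, tolerance = 1e-6)
  expect_equal(res$weights[1, ], c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(res$output[1, 1], 1.5379, tolerance = 1e-4)

  # all-zero queries: uniform weights, every output row = column mean of V
  V <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2)
  res0 <- scaledDotAttention(matrix(0, 3, 2), matrix(rnorm(6), 3, 2), V)
  for (i in 1:3)
    expect_equal(res0$output[i, ], colMeans(V), tolerance = 1e-12)

  expect_error(scaledDotAttention(matrix(nrow = 2, ncol = 0),
                                  matrix(nrow = 2, ncol = 0),
                                  matrix(nrow = 2, ncol = 0)),
               class = "dsynet_shape_error")

  # attention weight rows are probability distributions
  set.seed(2)
  r <- scaledDotAttention(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3),
                          matrix(rnorm(12), 4, 3))
  expect_equal(rowSums(r$weights), rep(1, 4), tolerance = 1e-6)
})

test_that("the default architecture matches the printed dimensions", {
  cfg <- modelConfig()
  expect_equal(cfg$panelSize, 2401L)
  expect_equal(cfg$reducedDim, 512L)
  expect_equal(cfg$nTokens, 3L)
  model <- synergyModel(cfg)
  expect_equal(dim(model@params$Wr), c(2401L, 512L))
  # no positional-encoding parameters anywhere
  expect_false(any(grepl("pos", names(unlist(model@params)), ignore.case = TRUE)))
})

test_that("input reduction shares one gene-to-latent map across columns", {
  cfg <- modelConfig(panelSize = 40L, reducedDim = 8L, nHeads = 2L,
                     ffDim = 16L, headHidden = 8L, nTokens = 3L, seed = 1L)
  model <- synergyModel(cfg)
  genes <- sprintf("g%02d", 1:40)
  m <- matrix(rnorm(120), 40, 3, dimnames = list(genes, NULL))
  m[, 2] <- m[, 1]                     # identical drug columns
  sample <- new("SampleTensor", mat = m,
                columnRoles = c("drugA", "drugB", "cell_dependency"),
                label = NA_real_, meta = list())
  red <- reduceInput(sample, model)
  expect_equal(dim(red), c(8L, 3L))
  expect_identical(red[, 1], red[, 2])  # shared weights
  # zero parameters map everything to zero
  model0 <- model
  model0@params$Wr[] <- 0
  model0@params$br[] <- 0
  expect_true(all(reduceInput(sample, model0) == 0))
  # shape mismatch is rejected
  bad <- new("SampleTensor", mat = m[1:20, ],
             columnRoles = c("drugA", "drugB", "cell_dependency"),
             label = NA_real_, meta = list())
  expect_error(reduceInput(bad, model), class = "dsynet_shape_error")
})

test_that("inference is deterministic and constant networks are constant", {
  study <- tinyStudy()
  cfg <- tinyModelConfig()
  model <- synergyModel(cfg)
  recs <- study$records[1:4, ]
  samples <- buildSampleSet(recs, study$profiles, study$depStd)
  p1 <- predictSynergy(model, samples)
  p2 <- predictSynergy(model, samples)
  expect_identical(p1, p2)             # bit-identical at inference
  expect_length(p1, 4L)
  expect_true(all(is.finite(p1)))

  # zero all parameters except the final bias: output is that bias
  modelC <- model
  modelC@params <- dsynet:::mapParams(function(a, b, c) a * 0, modelC@params)
  nH <- length(modelC@params$head)
  modelC@params$head[[nH]]$c <- 4.2
  expect_equal(unname(predictSynergy(modelC, samples)), rep(4.2, 4L))
})

test_that("the encoder is permutation-equivariant over tokens", {
  study <- tinyStudy()
  model <- synergyModel(tinyModelConfig())
  recs <- study$records[7, ]
  s <- buildSampleSet(recs, study$profiles, study$depStd)[[1]]
  sSwap <- s
  sSwap@mat <- s@mat[, c(2, 1, 3)]
  colnames(sSwap@mat) <- colnames(s@mat)
  encA <- encodeSample(s, model)
  encB <- encodeSample(sSwap, model)
  # swapping drugA/drugB permutes the encoder outputs identically
  expect_equal(encB[, 1], encA[, 2], tolerance = 1e-10)
  expect_equal(encB[, 2], encA[, 1], tolerance = 1e-10)
  expect_equal(encB[, 3], encA[, 3], tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- modelConfig(panelSize = 7L, reducedDim = 4L, nHeads = 2L,
                     nLayers = 2L, ffDim = 5L, dropout = 0,
                     headHidden = 6L, nTokens = 3L, seed = 3L)
  params <- dsynet:::initParams(cfg)
  set.seed(9)
  B <- 2L
  tokens <- lapply(1:3, function(i) matrix(rnorm(B * 7), B, 7))
  y <- rnorm(B)
  lossFn <- function(p) mean((dsynet:::nnForward(p, tokens, cfg)$out - y)^2)
  fw <- dsynet:::nnForward(params, tokens, cfg)
  bw <- dsynet:::nnBackward(params, fw$cache, 2 * (fw$out - y) / B, cfg)
  getL <- function(p, path) Reduce(`[[`, path, p)
  setL <- function(p, path, v) {
    if (length(path) == 1) { p[[path[[1]]]] <- v; return(p) }
    p[[path[[1]]]] <- setL(p[[path[[1]]]], path[-1], v)
    p
  }
  eps <- 1e-6
  leaves <- list(
    list(list("Wr"), c(3, 2)), list(list("br"), 1),
    list(list("layers", 1, "Wq"), c(1, 2)),
    list(list("layers", 1, "Wk"), c(2, 2)),
    list(list("layers", 2, "Wv"), c(2, 3)),
    list(list("layers", 2, "Wo"), c(4, 1)),
    list(list("layers", 1, "g1"), 2),
    list(list("layers", 1, "W1"), c(3, 4)),
    list(list("layers", 2, "W2"), c(5, 2)),
    list(list("layers", 1, "g2"), 3),
    list(list("layers", 2, "bq"), 2),
    list(list("head", 1, "U"), c(7, 2)),
    list(list("head", 2, "U"), c(4, 1)))
  for (lf in leaves) {
    path <- lf[[1]]; idx <- lf[[2]]
    pert <- function(d) {
      v <- getL(params, path)
      if (length(idx) == 2) v[idx[1], idx[2]] <- v[idx[1], idx[2]] + d
      else v[idx] <- v[idx] + d
      setL(params, path, v)
    }
    num <- (lossFn(pert(eps)) - lossFn(pert(-eps))) / (2 * eps)
    g <- getL(bw$grads, path)
    ana <- if (length(idx) == 2) g[idx[1], idx[2]] else g[idx]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
  }
  # gradient with respect to the input (needed by expected gradients)
  tp <- tokens; tp[[2]][1, 4] <- tp[[2]][1, 4] + eps
  tm <- tokens; tm[[2]][1, 4] <- tm[[2]][1, 4] - eps
  num <- (mean((dsynet:::nnForward(params, tp, cfg)$out - y)^2) -
          mean((dsynet:::nnForward(params, tm, cfg)$out - y)^2)) / (2 * eps)
  expect_lt(abs(num - bw$dTokens[[2]][1, 4]) / (abs(num) + 1e-8), 1e-5)
})

test_that("one small optimization step decreases the loss", {
  cfg <- modelConfig(panelSize = 30L, reducedDim = 8L, nHeads = 2L,
                     ffDim = 16L, dropout = 0, headHidden = 8L,
                     nTokens = 3L, seed = 5L, lr = 1e-4)
  params <- dsynet:::initParams(cfg)
  set.seed(1)
  tokens <- lapply(1:3, function(i) matrix(rnorm(30), 1, 30))
  y <- 2.5
  lossOf <- function(p) (dsynet:::nnForward(p, tokens, cfg)$out - y)^2
  fw <- dsynet:::nnForward(params, tokens, cfg)
  bw <- dsynet:::nnBackward(params, fw$cache, 2 * (fw$out - y), cfg)
  newParams <- dsynet:::mapParams(function(p, g, .) p - 1e-4 * g,
                                  params, bw$grads)
  expect_lt(lossOf(newParams), lossOf(params))
})

test_that("the model overfits a small sample set", {
  study <- tinyStudy()
  recs <- study$records[1:32, ]
  cfg <- modelConfig(panelSize = 80L, reducedDim = 16L, nHeads = 4L,
                     ffDim = 32L, dropout = 0, headHidden = c(32L, 16L),
                     nTokens = 3L, seed = 11L, lr = 5e-3, batchSize = 32L,
                     epochs = 500L)
  fit <- trainFold(recs, list(train = recs$id, validation = integer(),
                              test = integer()),
                   study$profiles, study$depStd, config = cfg,
                   augment = FALSE)
  samples <- buildSampleSet(recs, study$profiles, study$depStd)
  pred <- predictSynergy(fit$model, samples)
  expect_lt(mean((pred - recs$score)^2), 1.0)
  # training loss decreases over the run
  h <- fit$history
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
})

test_that("variant models concatenate per-drug extras before the head", {
  cfg <- modelConfig(panelSize = 30L, reducedDim = 8L, nHeads = 2L,
                     ffDim = 16L, dropout = 0, headHidden = 8L,
                     nTokens = 3L, seed = 5L, variant = "CI", extraDim = 4L)
  model <- synergyModel(cfg)
  # head input width = flattened encoder + 2 x extraDim
  expect_equal(nrow(model@params$head[[1]]$U), 3L * 8L + 2L * 4L)
  genes <- sprintf("g%02d", 1:30)
  m <- matrix(rnorm(90), 30, 3, dimnames = list(genes, NULL))
  s <- new("SampleTensor", mat = m,
           columnRoles = c("drugA", "drugB", "cell_dependency"),
           label = NA_real_, meta = list())
  extras <- matrix(rnorm(8), 1, 8)
  p <- predictSynergy(model, s, extras = extras)
  expect_true(is.finite(p))
  # missing extras is a structured error; base models refuse extras
  expect_error(predictSynergy(model, s), class = "dsynet_variant_error")
  base <- synergyModel(modelConfig(panelSize = 30L, reducedDim = 8L,
                                   nHeads = 2L, ffDim = 16L,
                                   headHidden = 8L, nTokens = 3L, seed = 5L))
  expect_error(predictSynergy(base, s, extras = extras),
               class = "dsynet_variant_error")
  # zero extras reduce the variant to its base-head behaviour on the
  # shared weights (extra inputs contribute nothing through zero columns)
  pz <- predictSynergy(model, s, extras = matrix(0, 1, 8))
  expect_true(is.finite(pz))
})

test_that("checkpoints round-trip through disk", {
  fit <- tinyTrainedFit()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "model.rds")
  writeModel(fit$model, f)
  back <- readModel(f)
  study <- tinyStudy()
  samples <- buildSampleSet(study$records[1:3, ], study$profiles, study$depStd)
  expect_identical(predictSynergy(fit$model, samples),
                   predictSynergy(back, samples))
})
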