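## Neural-network core: batched forward pass, analytic backpropagation and
## Adam updates for the synergy regression model.
##
## Layout: a sample is a genes x k matrix (k = 3 or 4 feature columns).
## The k columns are the transformer tokens. A batch of B samples is kept
## as a list of k token matrices, each B x p, so every dense operation is
## one matrix product over the whole batch; only the tiny k x k attention
## algebra is expanded per token pair (k^2 vectorized operations, never a
## per-sample loop). Gradients are validated against finite differences in
## the test suite.

LN_EPS <- 1e-5

## --- parameter initialization ---------------------------------------------

xavier <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

initParams <- function(config) {
  set.seed(config$seed)
  p <- config$panelSize; d <- config$reducedDim
  f <- config$ffDim; L <- config$nLayers
  params <- list(Wr = xavier(p, d), br = numeric(d))
  params$layers <- lapply(seq_len(L), function(l) list(
    Wq = xavier(d, d), bq = numeric(d),
    Wk = xavier(d, d), bk = numeric(d),
    Wv = xavier(d, d), bv = numeric(d),
    Wo = xavier(d, d), bo = numeric(d),
    g1 = rep(1, d), n1 = numeric(d),
    W1 = xavier(d, f), b1 = numeric(f),
    W2 = xavier(f, d), b2 = numeric(d),
    g2 = rep(1, d), n2 = numeric(d)))
  k <- config$nTokens
  inDim <- k * d + 2L * config$extraDim
  dims <- c(inDim, config$headHidden, 1L)
  params$head <- lapply(seq_len(length(dims) - 1L), function(i)
    list(U = xavier(dims[i], dims[i + 1L]), c = numeric(dims[i + 1L])))
  params
}

## --- elementwise recursion over nested parameter lists ---------------------

mapParams <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- mapParams(f, a[[i]],
                            if (!is.null(b)) b[[i]],
                            if (!is.null(c)) c[[i]])
    return(out)
  }
  f(a, b, c)
}

zeroLike <- function(params) mapParams(function(a, b, c) a * 0, params)

## --- primitive layers ------------------------------------------------------

layerNormForward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  Xhat <- Xc * inv
  Y <- sweep(sweep(Xhat, 2L, g, `*`), 2L, b, `+`)
  list(Y = Y, Xhat = Xhat, inv = inv)
}

layerNormBackward <- function(dY, cache, g) {
  Xhat <- cache$Xhat; inv <- cache$inv
  dG <- colSums(dY * Xhat)
  dB <- colSums(dY)
  dXhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- inv * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dG = dG, dB = dB)
}

softmaxRows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

dropoutMask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

## --- full forward pass -----------------------------------------------------

## tokens: list of k matrices (B x p). extras: B x (2*extraDim) or NULL.
nnForward <- function(params, tokens, config, extras = NULL,
                      training = FALSE) {
  k <- length(tokens)
  B <- nrow(tokens[[1]])
  d <- config$reducedDim
  nh <- config$nHeads
  dh <- d %/% nh
  rate <- if (training) config$dropout else 0
  cache <- list(tokens = tokens, k = k, B = B)
  H <- lapply(tokens, function(T) sweep(T %*% params$Wr, 2L, params$br, `+`))
  cache$H0 <- H
  cache$layers <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    pl <- params$layers[[l]]
    lc <- list(Hin = H)
    Q <- lapply(H, function(x) sweep(x %*% pl$Wq, 2L, pl$bq, `+`))
    K <- lapply(H, function(x) sweep(x %*% pl$Wk, 2L, pl$bk, `+`))
    V <- lapply(H, function(x) sweep(x %*% pl$Wv, 2L, pl$bv, `+`))
    lc$Q <- Q; lc$K <- K; lc$V <- V
    O <- lapply(seq_len(k), function(i) matrix(0, B, d))
    P <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ph <- vector("list", k)
      for (i in seq_len(k)) {
        S <- matrix(0, B, k)
        for (j in seq_len(k))
          S[, j] <- rowSums(Q[[i]][, cols, drop = FALSE] *
                            K[[j]][, cols, drop = FALSE]) / sqrt(dh)
        Pi <- softmaxRows(S)
        Ph[[i]] <- Pi
        acc <- matrix(0, B, dh)
        for (j in seq_len(k))
          acc <- acc + Pi[, j] * V[[j]][, cols, drop = FALSE]
        O[[i]][, cols] <- acc
      }
      P[[h]] <- Ph
    }
    lc$P <- P; lc$O <- O
    Att <- lapply(O, function(x) sweep(x %*% pl$Wo, 2L, pl$bo, `+`))
    R1 <- mapply(`+`, H, Att, SIMPLIFY = FALSE)
    ln1 <- lapply(R1, layerNormForward, g = pl$g1, b = pl$n1)
    N1 <- lapply(ln1, `[[`, "Y")
    lc$ln1 <- ln1
    Fpre <- lapply(N1, function(x) sweep(x %*% pl$W1, 2L, pl$b1, `+`))
    Frelu <- lapply(Fpre, pmax, 0)
    lc$Frelu <- Frelu
    Fo <- lapply(Frelu, function(x) sweep(x %*% pl$W2, 2L, pl$b2, `+`))
    lc$ffMask <- lapply(seq_len(k), function(i) dropoutMask(B, d, rate))
    if (rate > 0)
      Fo <- mapply(function(x, m) x * m, Fo, lc$ffMask, SIMPLIFY = FALSE)
    R2 <- mapply(`+`, N1, Fo, SIMPLIFY = FALSE)
    ln2 <- lapply(R2, layerNormForward, g = pl$g2, b = pl$n2)
    lc$ln2 <- ln2
    H <- lapply(ln2, `[[`, "Y")
    cache$layers[[l]] <- lc
  }
  cache$Henc <- H
  Z <- do.call(cbind, H)
  if (!is.null(extras)) Z <- cbind(Z, extras)
  cache$extraWidth <- if (is.null(extras)) 0L else ncol(extras)
  cache$headZ <- list()
  cache$headMask <- list()
  nH <- length(params$head)
  for (i in seq_len(nH)) {
    cache$headZ[[i]] <- Z
    A <- sweep(Z %*% params$head[[i]]$U, 2L, params$head[[i]]$c, `+`)
    if (i < nH) {
      A <- pmax(A, 0)
      m <- dropoutMask(nrow(A), ncol(A), rate)
      cache$headMask[i] <- list(m)
      if (!is.null(m)) A <- A * m
    }
    Z <- A
  }
  list(out = as.numeric(Z), cache = cache)
}

## --- full backward pass ----------------------------------------------------

## dout: numeric length B (gradient of loss wrt scalar outputs).
nnBackward <- function(params, cache, dout, config) {
  k <- cache$k; B <- cache$B
  d <- config$reducedDim
  nh <- config$nHeads
  dh <- d %/% nh
  grads <- zeroLike(params)
  nH <- length(params$head)
  Zs <- cache$headZ
  dAct <- matrix(dout, B, 1L)     # gradient wrt output of layer nH
  for (i in rev(seq_len(nH))) {
    Z <- Zs[[i]]
    if (i < nH) {
      A <- sweep(Z %*% params$head[[i]]$U, 2L, params$head[[i]]$c, `+`)
      m <- cache$headMask[[i]]
      dPre <- dAct
      if (!is.null(m)) dPre <- dPre * m
      dPre <- dPre * (A > 0)
    } else dPre <- dAct
    grads$head[[i]]$U <- t(Z) %*% dPre
    grads$head[[i]]$c <- colSums(dPre)
    dAct <- dPre %*% t(params$head[[i]]$U)
  }
  dZ <- dAct
  ew <- cache$extraWidth
  dExtras <- if (ew > 0) dZ[, (k * d + 1L):(k * d + ew), drop = FALSE] else NULL
  dH <- lapply(seq_len(k), function(i)
    dZ[, ((i - 1L) * d + 1L):(i * d), drop = FALSE])
  for (l in rev(seq_along(params$layers))) {
    pl <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- grads$layers[[l]]
    ## layernorm 2
    dR2 <- vector("list", k)
    for (i in seq_len(k)) {
      lb <- layerNormBackward(dH[[i]], lc$ln2[[i]], pl$g2)
      dR2[[i]] <- lb$dX
      gl$g2 <- gl$g2 + lb$dG
      gl$n2 <- gl$n2 + lb$dB
    }
    ## feed-forward (+ dropout) and residual
    dN1 <- dR2
    for (i in seq_len(k)) {
      dFo <- dR2[[i]]
      if (!is.null(lc$ffMask[[i]])) dFo <- dFo * lc$ffMask[[i]]
      Fr <- lc$Frelu[[i]]
      gl$W2 <- gl$W2 + t(Fr) %*% dFo
      gl$b2 <- gl$b2 + colSums(dFo)
      dFr <- dFo %*% t(pl$W2)
      dFr <- dFr * (Fr > 0)
      N1i <- lc$ln1[[i]]$Y
      gl$W1 <- gl$W1 + t(N1i) %*% dFr
      gl$b1 <- gl$b1 + colSums(dFr)
      dN1[[i]] <- dN1[[i]] + dFr %*% t(pl$W1)
    }
    ## layernorm 1
    dR1 <- vector("list", k)
    for (i in seq_len(k)) {
      lb <- layerNormBackward(dN1[[i]], lc$ln1[[i]], pl$g1)
      dR1[[i]] <- lb$dX
      gl$g1 <- gl$g1 + lb$dG
      gl$n1 <- gl$n1 + lb$dB
    }
    ## residual: dR1 feeds both H and attention output
    dHin <- dR1
    dAtt <- dR1
    ## output projection
    dO <- vector("list", k)
    for (i in seq_len(k)) {
      gl$Wo <- gl$Wo + t(lc$O[[i]]) %*% dAtt[[i]]
      gl$bo <- gl$bo + colSums(dAtt[[i]])
      dO[[i]] <- dAtt[[i]] %*% t(pl$Wo)
    }
    ## attention core, per head
    dQ <- lapply(seq_len(k), function(i) matrix(0, B, d))
    dK <- lapply(seq_len(k), function(i) matrix(0, B, d))
    dV <- lapply(seq_len(k), function(i) matrix(0, B, d))
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      for (i in seq_len(k)) {
        Pi <- lc$P[[h]][[i]]
        dOh <- dO[[i]][, cols, drop = FALSE]
        dPi <- matrix(0, B, k)
        for (j in seq_len(k)) {
          dPi[, j] <- rowSums(dOh * lc$V[[j]][, cols, drop = FALSE])
          dV[[j]][, cols] <- dV[[j]][, cols, drop = FALSE] + Pi[, j] * dOh
        }
        dS <- Pi * (dPi - rowSums(dPi * Pi))
        for (j in seq_len(k)) {
          dQ[[i]][, cols] <- dQ[[i]][, cols, drop = FALSE] +
            dS[, j] / sqrt(dh) * lc$K[[j]][, cols, drop = FALSE]
          dK[[j]][, cols] <- dK[[j]][, cols, drop = FALSE] +
            dS[, j] / sqrt(dh) * lc$Q[[i]][, cols, drop = FALSE]
        }
      }
    }
    ## projections back to H
    for (i in seq_len(k)) {
      Hin <- lc$Hin[[i]]
      gl$Wq <- gl$Wq + t(Hin) %*% dQ[[i]]
      gl$bq <- gl$bq + colSums(dQ[[i]])
      gl$Wk <- gl$Wk + t(Hin) %*% dK[[i]]
      gl$bk <- gl$bk + colSums(dK[[i]])
      gl$Wv <- gl$Wv + t(Hin) %*% dV[[i]]
      gl$bv <- gl$bv + colSums(dV[[i]])
      dHin[[i]] <- dHin[[i]] + dQ[[i]] %*% t(pl$Wq) +
        dK[[i]] %*% t(pl$Wk) + dV[[i]] %*% t(pl$Wv)
    }
    grads$layers[[l]] <- gl
    dH <- dHin
  }
  ## reduction
  dTokens <- vector("list", k)
  for (i in seq_len(k)) {
    grads$Wr <- grads$Wr + t(cache$tokens[[i]]) %*% dH[[i]]
    grads$br <- grads$br + colSums(dH[[i]])
    dTokens[[i]] <- dH[[i]] %*% t(params$Wr)
  }
  list(grads = grads, dTokens = dTokens, dExtras = dExtras)
}

## --- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapParams(function(m, g, .) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- mapParams(function(v, g, .) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- mapParams(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}
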