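## The synergy regression model: per-column input dimension reduction, a
## positional-encoding-free self-attention transformer encoder over the
## feature columns, and a fully connected output head. Chemical-information
## (CI) and graph-neural-fingerprint (GNF) variants concatenate per-drug
## descriptor vectors with the flattened encoder output before the head.

#' Model configuration
#'
#' Architectural defaults follow the published architecture where it is
#' printed (2401-gene panel reduced to 512 latent dimensions, no positional
#' encoding); remaining hyperparameters are declared package defaults, all
#' overridable.
#'
#' @param panelSize gene panel size (default 2401).
#' @param reducedDim latent width after input reduction (default 512).
#' @param nHeads attention heads (must divide \code{reducedDim}).
#' @param nLayers encoder layers.
#' @param ffDim feed-forward width inside the encoder.
#' @param dropout dropout rate during training.
#' @param headHidden integer vector of fully-connected head widths.
#' @param variant \code{"base"}, \code{"CI"} or \code{"GNF"}.
#' @param extraDim per-drug extra feature width (CI/GNF variants).
#' @param nTokens number of input feature columns (3 single-cell-feature
#'   mode, 4 dual mode).
#' @param attentionOver token layout; only \code{"columns"} (tokens = the
#'   k feature columns) is supported.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @param lr,batchSize,epochs Adam learning rate, minibatch size, training
#'   epochs.
#' @return a list of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(panelSize = 2401L, reducedDim = 512L, nHeads = 8L,
                        nLayers = 1L, ffDim = 512L, dropout = 0.2,
                        headHidden = c(2048L, 512L), variant = c("base", "CI", "GNF"),
                        extraDim = 0L, nTokens = 3L,
                        attentionOver = "columns", seed = 1L,
                        lr = 1e-4, batchSize = 64L, epochs = 100L) {
  variant <- match.arg(variant)
  if (reducedDim > panelSize)
    dsynetStop("reducedDim must not exceed panelSize", "dsynet_config_error")
  if (reducedDim %% nHeads != 0)
    dsynetStop("nHeads must divide reducedDim", "dsynet_config_error")
  if (!nTokens %in% c(3L, 4L))
    dsynetStop("nTokens must be 3 or 4", "dsynet_config_error")
  if (!identical(attentionOver, "columns"))
    dsynetStop("only column-token attention is supported",
               "dsynet_config_error")
  if (variant != "base" && extraDim < 1)
    dsynetStop("CI/GNF variants need extraDim >= 1", "dsynet_config_error")
  if (variant == "base" && extraDim != 0)
    dsynetStop("base variant must have extraDim = 0", "dsynet_config_error")
  structure(list(panelSize = as.integer(panelSize),
                 reducedDim = as.integer(reducedDim),
                 nHeads = as.integer(nHeads), nLayers = as.integer(nLayers),
                 ffDim = as.integer(ffDim), dropout = dropout,
                 headHidden = as.integer(headHidden), variant = variant,
                 extraDim = as.integer(extraDim), nTokens = as.integer(nTokens),
                 attentionOver = attentionOver, seed = as.integer(seed),
                 lr = lr, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs)),
            class = "ModelConfig")
}

#' SynergyModel: parameters and configuration of the synergy predictor
#'
#' @slot params nested list of weight matrices (reduction, encoder layers,
#'   head). No positional-encoding parameters exist anywhere in the model.
#' @slot config a \code{\link{modelConfig}} list.
#' @slot labelCenter,labelScale label standardization learned at training
#'   time (predictions are returned on the original score scale).
#' @slot trained logical.
#' @exportClass SynergyModel
setClass("SynergyModel",
  representation(params = "list", config = "list",
                 labelCenter = "numeric", labelScale = "numeric",
                 trained = "logical"))

setValidity("SynergyModel", function(object) {
  if (!is.null(object@params$positional) )
    return("model must not carry positional-encoding parameters")
  flat <- unlist(object@params)
  if (length(flat) && any(!is.finite(flat))) return("non-finite parameters")
  TRUE
})

setMethod("show", "SynergyModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SynergyModel (%s): panel %d -> %d, %d layer(s) x %d head(s), head [%s]%s\n",
    cfg$variant, cfg$panelSize, cfg$reducedDim, cfg$nLayers, cfg$nHeads,
    paste(cfg$headHidden, collapse = ", "),
    if (object@trained) " [trained]" else " [untrained]"))
})

#' Initialize a synergy model
#'
#' @param config a \code{\link{modelConfig}}.
#' @return an untrained \code{\linkS4class{SynergyModel}} with seeded
#'   Xavier-initialized parameters.
#' @export
synergyModel <- function(config = modelConfig()) {
  new("SynergyModel", params = initParams(config), config = unclass(config),
      labelCenter = 0, labelScale = 1, trained = FALSE)
}

#' Model configuration accessor
#' @param x a \code{SynergyModel}.
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname modelConfigOf
#' @export
setMethod("modelConfigOf", "SynergyModel", function(x) x@config)

#' Scaled dot-product attention
#'
#' Computes \code{softmax(Q K^T / sqrt(d)) V} with the softmax taken
#' row-wise, so each token's attention weights form a probability
#' distribution.
#'
#' @param Q,K,V token x d matrices sharing their dimensions.
#' @return list with \code{output} (token x d matrix) and \code{weights}
#'   (token x token attention matrix, rows summing to 1).
#' @examples
#' scaledDotAttention(matrix(1), matrix(1), matrix(5))$output  # single token -> V
#' @export
scaledDotAttention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d <- ncol(Q)
  if (d == 0L) dsynetStop("attention width d must be positive",
                          "dsynet_shape_error")
  if (!all(dim(K) == dim(Q)) || nrow(V) != nrow(K) || ncol(V) != d)
    dsynetStop("Q, K, V must share token count and width",
               "dsynet_shape_error")
  W <- softmaxRows(Q %*% t(K) / sqrt(d))
  list(output = W %*% V, weights = W)
}

## Build the token list (length k of B x p matrices) from sample tensors.
tensorsToTokens <- function(samples) {
  k <- ncol(samples[[1]]@mat)
  p <- nrow(samples[[1]]@mat)
  B <- length(samples)
  lapply(seq_len(k), function(i) {
    T <- matrix(0, B, p)
    for (b in seq_len(B)) T[b, ] <- samples[[b]]@mat[, i]
    T
  })
}

checkSampleModel <- function(sample, model) {
  cfg <- model@config
  if (nrow(sample@mat) != cfg$panelSize)
    dsynetStop(sprintf("sample has %d gene rows but the model expects %d",
                       nrow(sample@mat), cfg$panelSize),
               "dsynet_shape_error")
  if (ncol(sample@mat) != cfg$nTokens)
    dsynetStop(sprintf("sample has %d columns but the model expects %d",
                       ncol(sample@mat), cfg$nTokens), "dsynet_shape_error")
}

#' Reduce a sample tensor into the model's latent space
#'
#' Applies the shared single-layer reduction (one gene-to-latent map used
#' for every feature column) to a genes x k sample, yielding the
#' reducedDim x k matrix the transformer consumes.
#'
#' @param sample a \code{\linkS4class{SampleTensor}}.
#' @param model a \code{\linkS4class{SynergyModel}}.
#' @return reducedDim x k numeric matrix.
#' @export
reduceInput <- function(sample, model) {
  checkSampleModel(sample, model)
  out <- t(sweep(t(sample@mat) %*% model@params$Wr, 2L, model@params$br, `+`))
  colnames(out) <- sample@columnRoles
  out
}

#' Encoder output for a sample (pre-flatten)
#'
#' Runs reduction + transformer encoder and returns the k token embeddings
#' before the fully connected head. Exposed for permutation-equivariance
#' audits: with no positional encoding, permuting input columns permutes
#' these embeddings identically.
#'
#' @param sample a \code{\linkS4class{SampleTensor}}.
#' @param model a \code{\linkS4class{SynergyModel}}.
#' @return reducedDim x k matrix of encoder outputs.
#' @export
encodeSample <- function(sample, model) {
  checkSampleModel(sample, model)
  fw <- nnForward(model@params, tensorsToTokens(list(sample)), model@config)
  enc <- vapply(fw$cache$Henc, function(h) h[1, ],
                numeric(model@config$reducedDim))
  colnames(enc) <- sample@columnRoles
  enc
}

#' Predict synergy scores
#'
#' Deterministic inference (dropout disabled): one finite scalar per
#' sample, on the original synergy-score scale.
#'
#' @param model a \code{\linkS4class{SynergyModel}}.
#' @param samples a \code{\linkS4class{SampleTensor}} or list of them.
#' @param extras optional B x (2*extraDim) matrix of per-drug descriptor
#'   concatenations (CI/GNF variants; required there, forbidden for base).
#' @return numeric vector of predicted synergy scores.
#' @export
predictSynergy <- function(model, samples, extras = NULL) {
  if (is(samples, "SampleTensor")) samples <- list(samples)
  for (s in samples) checkSampleModel(s, model)
  cfg <- model@config
  if (cfg$variant %in% c("CI", "GNF")) {
    if (is.null(extras))
      dsynetStop(sprintf("variant %s requires extra per-drug features",
                         cfg$variant), "dsynet_variant_error")
    extras <- as.matrix(extras)
    if (nrow(extras) != length(samples) || ncol(extras) != 2L * cfg$extraDim)
      dsynetStop("extras must be B x (2 * extraDim)", "dsynet_shape_error")
  } else if (!is.null(extras)) {
    dsynetStop("base variant takes no extra features", "dsynet_variant_error")
  }
  fw <- nnForward(model@params, tensorsToTokens(samples), cfg,
                  extras = extras, training = FALSE)
  fw$out * model@labelScale + model@labelCenter
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameters with the embedded configuration and a
#' format version tag.
#'
#' @param model a \code{\linkS4class{SynergyModel}}.
#' @param path checkpoint file path.
#' @export
writeModel <- function(model, path) {
  saveRDS(list(format = "dsynet-checkpoint-1", params = model@params,
               config = model@config, labelCenter = model@labelCenter,
               labelScale = model@labelScale, trained = model@trained),
          path)
  invisible(path)
}

#' @rdname writeModel
#' @return \code{readModel}: the restored \code{SynergyModel}.
#' @export
readModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dsynet-checkpoint-1"))
    dsynetStop("unrecognized checkpoint format", "dsynet_input_error")
  new("SynergyModel", params = x$params, config = x$config,
      labelCenter = x$labelCenter, labelScale = x$labelScale,
      trained = x$trained)
}
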