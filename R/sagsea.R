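## Shapley Additive Gene Set Enrichment Analysis (SA-GSEA).
##
## Every input feature of the synergy model corresponds to a gene, so a
## per-feature attribution of one prediction is a per-gene importance
## profile. Attributions are estimated with expected gradients (integrated
## gradients averaged over a k-means-summarized background of training
## samples, repeated with distinct seeds and averaged), which satisfies the
## additivity/completeness axiom: attributions sum to the model output
## minus the background expectation. Genes ranked by attribution then feed
## a weighted Kolmogorov-Smirnov gene set enrichment statistic with a
## set-resampling permutation null.

#' Attribution settings
#'
#' @param backgroundSummaryK number of k-means centroids summarizing the
#'   training data as the attribution background (default 25).
#' @param nRepeats independent estimation repeats to average (default 10).
#' @param integrationSteps gradient-integration steps per background
#'   reference (default 128; additivity holds within 5 percent relative
#'   tolerance from 128 up).
#' @param seed integer seed.
#' @return list of class \code{"AttributionConfig"}.
#' @export
attributionConfig <- function(backgroundSummaryK = 25L, nRepeats = 10L,
                              integrationSteps = 128L, seed = 1L) {
  vals <- c(backgroundSummaryK, nRepeats, integrationSteps)
  if (any(vals < 1))
    dsynetStop("attribution config values must be positive",
               "dsynet_config_error")
  structure(list(backgroundSummaryK = as.integer(backgroundSummaryK),
                 nRepeats = as.integer(nRepeats),
                 integrationSteps = as.integer(integrationSteps),
                 seed = as.integer(seed)),
            class = "AttributionConfig")
}

#' AttributionReport: per-gene, per-column attributions of one prediction
#'
#' @slot attributions genes x k matrix of attribution values.
#' @slot modelOutput the explained prediction.
#' @slot backgroundExpectation mean model output over the background.
#' @slot config the \code{\link{attributionConfig}} used.
#' @exportClass AttributionReport
setClass("AttributionReport",
  representation(attributions = "matrix", modelOutput = "numeric",
                 backgroundExpectation = "numeric", config = "list"))

setMethod("show", "AttributionReport", function(object) {
  tot <- sum(object@attributions)
  cat(sprintf(
    "AttributionReport: %d genes x %d columns; f(x) = %.4g, E[f(bg)] = %.4g, sum(attr) = %.4g\n",
    nrow(object@attributions), ncol(object@attributions),
    object@modelOutput, object@backgroundExpectation, tot))
})

#' Attribution matrix accessor
#' @param x an \code{AttributionReport}.
#' @export
setGeneric("attributions", function(x) standardGeneric("attributions"))

#' @rdname attributions
#' @export
setMethod("attributions", "AttributionReport", function(x) x@attributions)

#' Summarize training samples into k-means background references
#'
#' @param samples list of \code{\linkS4class{SampleTensor}}s.
#' @param k number of centroids (capped at the sample count).
#' @param seed integer seed for k-means initialization.
#' @return list of genes x k matrices (the centroids reshaped to sample
#'   layout).
#' @export
backgroundCentroids <- function(samples, k = 25L, seed = 1L) {
  stopifnot(length(samples) >= 1L)
  dims <- dim(samples[[1]]@mat)
  flat <- t(vapply(samples, function(s) as.numeric(s@mat),
                   numeric(prod(dims))))
  k <- min(k, nrow(unique(flat)))
  set.seed(seed)
  centers <- if (k >= nrow(flat)) flat else
    stats::kmeans(flat, centers = k, nstart = 5L, iter.max = 50L)$centers
  lapply(seq_len(nrow(centers)), function(i)
    matrix(centers[i, ], dims[1], dims[2],
           dimnames = dimnames(samples[[1]]@mat)))
}

## Batched value+input-gradient evaluation of a SynergyModel on a list of
## genes x k matrices.
modelValueGrad <- function(model, inputs) {
  k <- ncol(inputs[[1]])
  B <- length(inputs)
  p <- nrow(inputs[[1]])
  tokens <- lapply(seq_len(k), function(i) {
    T <- matrix(0, B, p)
    for (b in seq_len(B)) T[b, ] <- inputs[[b]][, i]
    T
  })
  fw <- nnForward(model@params, tokens, model@config, training = FALSE)
  bw <- nnBackward(model@params, fw$cache, rep(1, B), model@config)
  grads <- lapply(seq_len(B), function(b) {
    G <- matrix(0, p, k)
    for (i in seq_len(k)) G[, i] <- bw$dTokens[[i]][b, ]
    G * model@labelScale
  })
  list(values = fw$out * model@labelScale + model@labelCenter,
       grads = grads)
}

## Core expected-gradients estimator over an arbitrary valueGrad oracle.
## valueGrad(list of inputs) -> list(values, grads); x, refs: matrices of
## identical shape.
expectedGradients <- function(valueGrad, x, refs, steps, nRepeats, seed) {
  acc <- x * 0
  set.seed(seed)
  for (rep in seq_len(nRepeats)) {
    u <- stats::runif(1)
    alphas <- (seq_len(steps) - u) / steps   # randomized midpoint grid
    est <- x * 0
    for (b in refs) {
      pts <- lapply(alphas, function(a) b + a * (x - b))
      vg <- valueGrad(pts)
      gbar <- Reduce(`+`, vg$grads) / steps
      est <- est + (x - b) * gbar
    }
    acc <- acc + est / length(refs)
  }
  acc / nRepeats
}

#' Compute per-gene attributions of one prediction
#'
#' Expected-gradients estimate of the Shapley-style contribution of every
#' input feature (gene x column) to the model's output for \code{sample},
#' relative to a background of training-data centroids. The estimate is
#' repeated \code{nRepeats} times with distinct integration offsets and
#' averaged. Additivity (sum of attributions = prediction - background
#' expectation) holds up to integration error.
#'
#' @param model a trained \code{\linkS4class{SynergyModel}}.
#' @param sample the \code{\linkS4class{SampleTensor}} to explain.
#' @param background list of background reference matrices, e.g. from
#'   \code{\link{backgroundCentroids}}.
#' @param config an \code{\link{attributionConfig}}.
#' @return an \code{\linkS4class{AttributionReport}}.
#' @export
computeAttributions <- function(model, sample, background,
                                config = attributionConfig()) {
  stopifnot(is(model, "SynergyModel"), is(sample, "SampleTensor"))
  if (!model@trained)
    dsynetStop("model must be trained before attribution",
               "dsynet_model_error")
  if (any(!is.finite(unlist(model@params))))
    dsynetStop("model parameters are not finite", "dsynet_model_error")
  x <- sample@mat
  vg <- function(inputs) modelValueGrad(model, inputs)
  attr <- expectedGradients(vg, x, background,
                            steps = config$integrationSteps,
                            nRepeats = config$nRepeats,
                            seed = config$seed)
  dimnames(attr) <- dimnames(x)
  out <- predictSynergy(model, sample)
  bg <- mean(modelValueGrad(model, background)$values)
  new("AttributionReport", attributions = attr, modelOutput = out,
      backgroundExpectation = bg, config = unclass(config))
}

#' Rank genes by their attribution in one column
#'
#' @param report an \code{\linkS4class{AttributionReport}}.
#' @param column column name (e.g. \code{"cell_dependency"} for cell-line
#'   SA-GSEA, \code{"drugA"}/\code{"drugB"} for target-importance reports)
#'   or index.
#' @return data.frame with columns \code{gene}, \code{score}, sorted by
#'   score descending, ties broken lexicographically by gene.
#' @export
rankGenes <- function(report, column) {
  stopifnot(is(report, "AttributionReport"))
  A <- report@attributions
  if (is.character(column) && !column %in% colnames(A))
    dsynetStop(paste("no attribution column", column), "dsynet_input_error")
  s <- A[, column]
  ord <- order(-s, names(s))
  data.frame(gene = names(s)[ord], score = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked gene list; genes in the set increment the running
#' sum by |score|^p normalized by the sum of |score|^p over set members,
#' genes outside decrement it by 1/(N - N_hit). The enrichment score is
#' the running sum's maximum deviation from zero (signed). weightP = 0
#' gives the classic unweighted statistic; the default 1 weights hits by
#' their attribution magnitude.
#'
#' @param ranked data.frame from \code{\link{rankGenes}} (columns
#'   \code{gene}, \code{score}), already sorted.
#' @param geneSet character vector of member genes.
#' @param weightP weighting exponent p (default 1).
#' @return list: \code{es}, \code{runningSum} (length N), \code{hits}
#'   (logical length N).
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hits <- genes %in% geneSet
  nHit <- sum(hits)
  if (nHit == 0L)
    dsynetStop("gene set does not intersect the ranked list",
               "dsynet_enrichment_error")
  if (nHit == N)
    dsynetStop("gene set equals the ranked universe", "dsynet_enrichment_error")
  w <- abs(ranked$score)^weightP
  wHit <- sum(w[hits])
  inc <- numeric(N)
  if (wHit == 0) {
    inc[hits] <- 1 / nHit          # all-zero scores: fall back to unweighted
  } else {
    inc[hits] <- w[hits] / wHit
  }
  inc[!hits] <- -1 / (N - nHit)
  rs <- cumsum(inc)
  es <- rs[which.max(abs(rs))]
  list(es = es, runningSum = rs, hits = hits)
}

#' Permutation significance of an enrichment score
#'
#' The null distribution is built from random gene sets of the same size
#' drawn from the ranked universe (set resampling; a per-sample phenotype
#' permutation is meaningless for a single explained prediction). The
#' p-value uses the add-one estimator p = (1 + #\{|ES_null| >= |ES|\}) /
#' (nPermutations + 1), so it is never below 1/(nPermutations + 1). NES
#' divides the observed ES by the mean |ES_null| of null scores sharing
#' its sign.
#'
#' @param ranked sorted data.frame from \code{\link{rankGenes}}.
#' @param geneSet character vector of member genes.
#' @param nPermutations number of null sets (>= 100).
#' @param seed integer seed.
#' @param weightP weighting exponent.
#' @return data.frame row: \code{es}, \code{nes}, \code{p},
#'   \code{nPermutations}, \code{weightP}, \code{degenerate}.
#' @export
permutationSignificance <- function(ranked, geneSet, nPermutations = 1000L,
                                    seed = 1L, weightP = 1) {
  if (nPermutations < 100L)
    dsynetStop("use at least 100 permutations", "dsynet_config_error")
  obs <- enrichmentScore(ranked, geneSet, weightP)
  m <- sum(ranked$gene %in% geneSet)
  set.seed(seed)
  nullEs <- vapply(seq_len(nPermutations), function(i) {
    rs <- enrichmentScore(ranked, sample(ranked$gene, m), weightP)
    rs$es
  }, 0)
  degenerate <- length(unique(round(nullEs, 12))) == 1L
  p <- if (degenerate) 1 else
    (1 + sum(abs(nullEs) >= abs(obs$es))) / (nPermutations + 1)
  sameSign <- nullEs[sign(nullEs) == sign(obs$es)]
  nes <- if (length(sameSign)) obs$es / mean(abs(sameSign)) else NA_real_
  data.frame(es = obs$es, nes = nes, p = p,
             nPermutations = as.integer(nPermutations),
             weightP = weightP, degenerate = degenerate)
}

#' SA-GSEA over a gene set collection
#'
#' Ranks genes by their attribution in one column and tests every gene
#' set for enrichment with permutation significance.
#'
#' @param report an \code{\linkS4class{AttributionReport}}.
#' @param geneSets named list of character vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @param column attribution column to rank (default the first cell
#'   feature column).
#' @param nPermutations,seed,weightP see
#'   \code{\link{permutationSignificance}}.
#' @return data.frame with one row per gene set, sorted by p then |NES|
#'   descending, with a Benjamini-Hochberg \code{padj} column.
#' @export
saGsea <- function(report, geneSets, column = NULL, nPermutations = 1000L,
                   seed = 1L, weightP = 1) {
  if (is.null(column)) {
    cells <- grep("^cell_", colnames(report@attributions), value = TRUE)
    column <- if (length(cells)) cells[1] else colnames(report@attributions)[1]
  }
  ranked <- rankGenes(report, column)
  rows <- lapply(names(geneSets), function(nm) {
    res <- try(permutationSignificance(ranked, geneSets[[nm]],
                                       nPermutations, seed, weightP),
               silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    cbind(data.frame(geneSet = nm, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    dsynetStop("no gene set overlaps the ranked universe",
               "dsynet_enrichment_error")
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, -abs(out$nes)), ]
}

#' Read / write GMT gene set files
#'
#' GMT: one set per line, tab-separated: name, description, members.
#'
#' @param path file path.
#' @return \code{readGMT}: named list of character vectors with a
#'   \code{"descriptions"} attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    dsynetStop(sprintf("malformed GMT line %d (need name, description, members)",
                       bad[1]), "dsynet_input_error")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param descriptions optional named descriptions (defaults to set names).
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
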