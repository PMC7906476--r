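## Gene panel assembly, cell-line feature imputation/standardization, and
## per-sample input tensors.

#' Select the model gene panel from drug targets and cancer genes
#'
#' The panel is the union of drug-target genes and annotated cancer genes
#' (drug targets first, then cancer-only genes, alphabetical within each
#' group), truncated or padded to \code{panelSize}. Padding with synthetic
#' placeholder gene symbols is only allowed in synthetic mode, so the
#' full-scale default of 2401 genes stays testable without real gene
#' annotation files.
#'
#' @param targets drug-target table (long data.frame or binary matrix, see
#'   \code{\link{propagateDrugs}}).
#' @param cancerGenes character vector of cancer-annotated gene symbols.
#' @param panelSize target panel size (default 2401).
#' @param allowPadding permit synthetic placeholder genes
#'   (\code{"PAD0001"}, ...) when the union is smaller than
#'   \code{panelSize}.
#' @return a \code{\linkS4class{GenePanel}}. Truncation emits a warning.
#' @export
selectGenePanel <- function(targets, cancerGenes, panelSize = 2401L,
                            allowPadding = FALSE) {
  tg <- sort(unique(normalizeTargetTable(targets)$gene))
  cg <- sort(unique(as.character(cancerGenes)))
  if (length(tg) == 0L && length(cg) == 0L)
    dsynetStop("both target and cancer gene lists are empty",
               "dsynet_input_error")
  genes <- c(tg, setdiff(cg, tg))
  prov <- c(ifelse(tg %in% cg, "both", "drug_target"),
            rep("cancer_gene", length(setdiff(cg, tg))))
  if (length(genes) > panelSize) {
    warning(sprintf("gene panel truncated from %d to %d genes",
                    length(genes), panelSize))
    genes <- genes[seq_len(panelSize)]
    prov <- prov[seq_len(panelSize)]
  } else if (length(genes) < panelSize) {
    if (!allowPadding)
      dsynetStop(sprintf(
        "only %d genes available for a panel of %d (enable padding for synthetic runs)",
        length(genes), panelSize), "dsynet_input_error")
    nPad <- panelSize - length(genes)
    genes <- c(genes, sprintf("PAD%04d", seq_len(nPad)))
    prov <- c(prov, rep("padding", nPad))
  }
  new("GenePanel", genes = genes, provenance = prov)
}

#' Construct a CellFeatureMatrix
#'
#' @param mat genes x cells numeric matrix with dimnames; NA entries are
#'   treated as missing.
#' @param featureKind \code{"expression"} or \code{"dependency"}.
#' @param panel optional \code{\linkS4class{GenePanel}}; rows are reordered
#'   to the panel, genes absent from \code{mat} (e.g. synthetic padding)
#'   become missing rows only if present — absent genes are an error unless
#'   they are padding genes, which get all-zero observed rows.
#' @return a \code{\linkS4class{CellFeatureMatrix}}.
#' @export
cellFeatureMatrix <- function(mat, featureKind = c("dependency", "expression"),
                              panel = NULL) {
  featureKind <- match.arg(featureKind)
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat)))
    dsynetStop("cell feature input must be a matrix with gene rownames and cell colnames",
               "dsynet_input_error")
  if (!is.null(panel)) {
    genes <- geneIds(panel)
    missing <- setdiff(genes, rownames(mat))
    pad <- genes[panel@provenance == "padding"]
    hard <- setdiff(missing, pad)
    if (length(hard))
      dsynetStop(paste("panel genes absent from feature matrix:",
                       paste(utils::head(hard, 5), collapse = ", ")),
                 "dsynet_input_error")
    if (length(missing)) {
      extra <- matrix(0, length(missing), ncol(mat),
                      dimnames = list(missing, colnames(mat)))
      mat <- rbind(mat, extra)
    }
    mat <- mat[genes, , drop = FALSE]
  }
  new("CellFeatureMatrix", mat = mat, featureKind = featureKind,
      missingMask = is.na(mat), standardized = FALSE,
      degenerateGenes = character())
}

#' Impute missing cell-line feature entries by chained linear regression
#'
#' Missing entries are initialized to their gene-row means; each incomplete
#' gene row is then regressed (ordinary least squares) on the most
#' correlated complete gene rows and its missing entries replaced by the
#' fit, iterating until the largest imputed-value change drops below
#' \code{tol} or \code{maxIter} is reached. Observed entries are never
#' touched.
#'
#' @param x a \code{\linkS4class{CellFeatureMatrix}}.
#' @param maxIter maximum sweeps (default 10).
#' @param tol convergence tolerance on imputed values (default 1e-4).
#' @param maxPredictors number of complete predictor rows per regression.
#' @return an imputed \code{\linkS4class{CellFeatureMatrix}} with an empty
#'   missing mask.
#' @export
imputeMissing <- function(x, maxIter = 10L, tol = 1e-4, maxPredictors = 5L) {
  stopifnot(is(x, "CellFeatureMatrix"))
  m <- x@mat
  mask <- x@missingMask
  if (!any(mask)) {
    out <- x
    out@missingMask <- mask
    return(out)
  }
  fullyMissing <- rownames(m)[rowSums(!mask) < 2]
  if (length(fullyMissing))
    dsynetStop(paste("genes with fewer than two observed values:",
                     paste(utils::head(fullyMissing, 5), collapse = ", ")),
               "dsynet_degenerate_input", genes = fullyMissing)
  emptyCells <- colnames(m)[colSums(!mask) < 1]
  if (length(emptyCells))
    dsynetStop(paste("cell lines with no observed values:",
                     paste(utils::head(emptyCells, 5), collapse = ", ")),
               "dsynet_degenerate_input")
  ## initial fill: gene-row means of observed entries
  rm0 <- rowMeans(m, na.rm = TRUE)
  for (i in which(rowSums(mask) > 0)) m[i, mask[i, ]] <- rm0[i]
  complete <- which(rowSums(mask) == 0)
  incomplete <- which(rowSums(mask) > 0)
  if (length(complete) == 0L) {
    ## nothing to regress on; row means stand
    out <- x; out@mat <- m; out@missingMask <- mask & FALSE
    return(out)
  }
  for (iter in seq_len(maxIter)) {
    delta <- 0
    for (i in incomplete) {
      obs <- !mask[i, ]
      y <- x@mat[i, obs]
      cand <- complete
      cors <- abs(apply(m[cand, obs, drop = FALSE], 1L,
                        function(z) suppressWarnings(stats::cor(z, y))))
      cors[is.na(cors)] <- 0
      nPred <- min(maxPredictors, length(cand), sum(obs) - 1L)
      if (nPred < 1L) next
      pred <- cand[order(cors, decreasing = TRUE)[seq_len(nPred)]]
      X <- cbind(1, t(m[pred, obs, drop = FALSE]))
      fit <- stats::lm.fit(X, y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      Xm <- cbind(1, t(m[pred, mask[i, ], drop = FALSE]))
      new <- as.numeric(Xm %*% beta)
      delta <- max(delta, max(abs(new - m[i, mask[i, ]])))
      m[i, mask[i, ]] <- new
    }
    if (delta < tol) break
  }
  out <- x
  out@mat <- m
  out@missingMask <- mask & FALSE
  out
}

#' Standardize cell-line features per gene
#'
#' Each gene row is centred and scaled to population standard deviation 1
#' across cell lines (features must be comparable across cells, so scaling
#' is per gene, not per cell line). Zero-variance rows are mapped to
#' all-zeros and recorded in \code{degenerateGenes}. Idempotent on
#' non-degenerate rows.
#'
#' @param x an imputed \code{\linkS4class{CellFeatureMatrix}}.
#' @return standardized \code{\linkS4class{CellFeatureMatrix}}.
#' @export
standardizeFeatures <- function(x) {
  stopifnot(is(x, "CellFeatureMatrix"))
  if (any(x@missingMask))
    dsynetStop("impute missing values before standardizing",
               "dsynet_input_error")
  m <- x@mat
  mu <- rowMeans(m)
  sd <- sqrt(rowMeans((m - mu)^2))      # population SD
  degenerate <- sd == 0
  m <- (m - mu) / ifelse(degenerate, 1, sd)
  m[degenerate, ] <- 0
  out <- x
  out@mat <- m
  out@standardized <- TRUE
  out@degenerateGenes <- union(x@degenerateGenes, rownames(m)[degenerate])
  out
}

#' Assemble one model input sample from drug profiles and cell features
#'
#' Builds the genes x k input matrix: the two propagated drug profiles
#' followed by the cell-line feature column(s). k = 3 in single
#' cell-feature mode and 4 when both dependency and expression are used.
#'
#' @param drugA,drugB drug identifiers present in \code{profiles}.
#' @param cell cell-line identifier.
#' @param profiles a \code{\linkS4class{DrugProfileSet}}.
#' @param dependency,expression \code{\linkS4class{CellFeatureMatrix}}
#'   objects; supply one for single mode, both for dual mode.
#' @param label optional synergy score.
#' @return a \code{\linkS4class{SampleTensor}}.
#' @export
assembleInput <- function(drugA, drugB, cell, profiles,
                          dependency = NULL, expression = NULL,
                          label = NA_real_) {
  stopifnot(is(profiles, "DrugProfileSet"))
  cols <- list()
  roles <- c("drugA", "drugB")
  genes <- profiles@geneIds
  for (d in c(drugA, drugB))
    if (!d %in% profiles@drugIds)
      dsynetStop(paste("no propagated profile for drug", d),
                 "dsynet_input_error")
  cols$drugA <- profiles@propagated[drugA, ]
  cols$drugB <- profiles@propagated[drugB, ]
  addCell <- function(fm, role) {
    if (is.null(fm)) return(NULL)
    stopifnot(is(fm, "CellFeatureMatrix"))
    if (!identical(rownames(fm@mat), genes))
      dsynetStop("cell feature matrix is not on the drug-profile gene panel",
                 "dsynet_panel_mismatch")
    if (!cell %in% colnames(fm@mat))
      dsynetStop(paste("unknown cell line", cell), "dsynet_input_error")
    fm@mat[, cell]
  }
  dep <- addCell(dependency, "cell_dependency")
  expr <- addCell(expression, "cell_expression")
  if (is.null(dep) && is.null(expr))
    dsynetStop("at least one cell feature matrix is required",
               "dsynet_input_error")
  if (!is.null(dep)) { cols$dep <- dep; roles <- c(roles, "cell_dependency") }
  if (!is.null(expr)) { cols$expr <- expr; roles <- c(roles, "cell_expression") }
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(genes, roles)
  new("SampleTensor", mat = mat, columnRoles = roles, label = label,
      meta = list(drugA = drugA, drugB = drugB, cell = cell))
}

#' Read a genes x cells feature matrix (CSV or TSV)
#'
#' Header row holds cell-line names; first column holds gene symbols;
#' \code{"NA"} or empty fields are missing.
#'
#' @param path file path; delimiter inferred from the extension
#'   (\code{.csv} comma, otherwise tab).
#' @param featureKind \code{"dependency"} or \code{"expression"}.
#' @param panel optional \code{\linkS4class{GenePanel}}.
#' @return a \code{\linkS4class{CellFeatureMatrix}}.
#' @export
readFeatureMatrix <- function(path, featureKind = "dependency", panel = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, na.strings = c("NA", ""))
  cellFeatureMatrix(as.matrix(tab), featureKind = featureKind, panel = panel)
}

#' Read a cancer gene list (one symbol per line)
#' @param path file path.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
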