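#' @import methods
#' @importFrom Matrix Matrix colSums rowSums t Diagonal sparseMatrix
NULL

## Classed conditions -------------------------------------------------------

#' Signal a structured dsynet error
#'
#' All user-facing failures in the package raise conditions of class
#' \code{"dsynet_error"} plus a more specific subclass, so callers (and the
#' command-line driver) can react programmatically instead of matching
#' message strings.
#'
#' @param msg character message.
#' @param class character, specific condition subclass.
#' @param ... named fields attached to the condition (e.g. offending ids).
#' @keywords internal
dsynetStop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "dsynet_error", "error")))
}

## GeneNetwork ---------------------------------------------------------------

#' GeneNetwork: weighted undirected gene-gene interaction graph
#'
#' Holds the raw protein-protein association graph behind the random-walk
#' transition matrix: an ordered gene panel, the confidence-weighted edge
#' list, and the symmetric non-negative adjacency matrix (zero diagonal).
#'
#' @slot geneIds character vector of unique gene symbols (defines node order).
#' @slot edges data.frame with columns \code{geneA}, \code{geneB},
#'   \code{confidence} (positive reals).
#' @slot adjacency symmetric sparse \code{Matrix} of edge confidences.
#' @exportClass GeneNetwork
setClass("GeneNetwork",
  representation(geneIds = "character", edges = "data.frame",
                 adjacency = "Matrix"))

setValidity("GeneNetwork", function(object) {
  n <- length(object@geneIds)
  if (n == 0L) return("network has no genes")
  if (anyDuplicated(object@geneIds)) return("gene ids must be unique")
  A <- object@adjacency
  if (nrow(A) != n || ncol(A) != n) return("adjacency dimension mismatch")
  if (any(A@x < 0)) return("edge confidences must be positive")
  if (nrow(object@edges) && any(object@edges$confidence <= 0))
    return("edge confidences must be positive")
  if (any(Matrix::diag(A) != 0)) return("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(as.numeric(A@x), as.numeric(Matrix::t(A)@x))) &&
      !Matrix::isSymmetric(A)) return("adjacency must be symmetric")
  TRUE
})

#' @describeIn GeneNetwork number of genes (nodes).
#' @param x,object a \code{GeneNetwork}.
#' @export
setMethod("length", "GeneNetwork", function(x) length(x@geneIds))

#' Gene identifiers of an object
#'
#' @param x an object with a gene panel (network, panel, feature matrix...).
#' @return character vector of gene symbols in panel order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneNetwork", function(x) x@geneIds)

#' Adjacency matrix accessor
#' @param x a \code{GeneNetwork}.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "GeneNetwork", function(x) x@adjacency)

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d genes, %d edges\n",
              length(object@geneIds), nrow(object@edges)))
  if (nrow(object@edges))
    cat(sprintf("  confidence range [%.3g, %.3g]\n",
                min(object@edges$confidence), max(object@edges$confidence)))
})

## TransitionMatrix ----------------------------------------------------------

#' TransitionMatrix: column-stochastic random-walk transition operator
#'
#' @slot W sparse non-negative matrix; each column sums to one.
#' @slot geneIds gene order (matches the source network).
#' @slot normalization normalization tag (\code{"column"}).
#' @slot danglingPolicy how isolated nodes were handled (\code{"self_loop"}
#'   or \code{"teleport"}).
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
  representation(W = "Matrix", geneIds = "character",
                 normalization = "character", danglingPolicy = "character"))

setValidity("TransitionMatrix", function(object) {
  n <- length(object@geneIds)
  if (nrow(object@W) != n || ncol(object@W) != n)
    return("W dimension mismatch with gene panel")
  cs <- Matrix::colSums(object@W)
  if (object@danglingPolicy == "self_loop") {
    if (any(abs(cs - 1) > 1e-10))
      return("columns must sum to 1 under self_loop policy")
  } else {
    nonzero <- cs > 0
    if (any(abs(cs[nonzero] - 1) > 1e-10))
      return("non-dangling columns must sum to 1")
  }
  TRUE
})

#' @rdname geneIds
#' @export
setMethod("geneIds", "TransitionMatrix", function(x) x@geneIds)

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d x %d, %s-normalized, dangling policy '%s'\n",
              nrow(object@W), ncol(object@W), object@normalization,
              object@danglingPolicy))
})

## DrugProfileSet ------------------------------------------------------------

#' DrugProfileSet: seed and propagated drug-target profiles
#'
#' One row per drug over a fixed gene panel. \code{seeds} holds the observed
#' binary drug-target vectors (e); \code{propagated} the random-walk-smoothed
#' genome-wide effect profiles (r).
#'
#' @slot drugIds character vector of drug identifiers.
#' @slot geneIds gene panel (column order of both matrices).
#' @slot seeds drugs x genes binary matrix.
#' @slot propagated drugs x genes matrix of propagated profiles in [0, 1].
#' @slot rejects character vector of drugs dropped for having no mapped
#'   target, plus attribute \code{"droppedTargets"} naming unmapped genes.
#' @exportClass DrugProfileSet
setClass("DrugProfileSet",
  representation(drugIds = "character", geneIds = "character",
                 seeds = "matrix", propagated = "matrix",
                 rejects = "character"))

setValidity("DrugProfileSet", function(object) {
  d <- length(object@drugIds); n <- length(object@geneIds)
  if (!all(dim(object@seeds) == c(d, n))) return("seed matrix dimension mismatch")
  if (!all(dim(object@propagated) == c(d, n)))
    return("propagated matrix dimension mismatch")
  if (!all(object@seeds %in% c(0, 1))) return("seeds must be binary")
  if (d > 0 && any(rowSums(object@seeds) < 1))
    return("every retained drug needs at least one target")
  TRUE
})

#' Drug identifiers of a profile set
#' @param x a \code{DrugProfileSet}.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugProfileSet", function(x) x@drugIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "DrugProfileSet", function(x) x@geneIds)

#' Propagated drug-effect profiles
#' @param x a \code{DrugProfileSet}.
#' @return drugs x genes numeric matrix.
#' @export
setGeneric("propagatedProfiles", function(x) standardGeneric("propagatedProfiles"))

#' @rdname propagatedProfiles
#' @export
setMethod("propagatedProfiles", "DrugProfileSet", function(x) x@propagated)

#' Observed (seed) drug-target profiles
#' @param x a \code{DrugProfileSet}.
#' @export
setGeneric("seedProfiles", function(x) standardGeneric("seedProfiles"))

#' @rdname seedProfiles
#' @export
setMethod("seedProfiles", "DrugProfileSet", function(x) x@seeds)

setMethod("show", "DrugProfileSet", function(object) {
  cat(sprintf("DrugProfileSet: %d drugs x %d genes (%d rejected)\n",
              length(object@drugIds), length(object@geneIds),
              length(object@rejects)))
})

## GenePanel -----------------------------------------------------------------

#' GenePanel: the ordered gene universe shared by all model inputs
#'
#' @slot genes ordered unique gene symbols.
#' @slot provenance per-gene tag: \code{"drug_target"}, \code{"cancer_gene"},
#'   \code{"both"} or \code{"padding"}.
#' @exportClass GenePanel
setClass("GenePanel",
  representation(genes = "character", provenance = "character"))

setValidity("GenePanel", function(object) {
  if (anyDuplicated(object@genes)) return("panel genes must be unique")
  if (length(object@provenance) != length(object@genes))
    return("provenance length mismatch")
  ok <- c("drug_target", "cancer_gene", "both", "padding")
  if (!all(object@provenance %in% ok))
    return("invalid provenance tag")
  TRUE
})

#' @rdname geneIds
#' @export
setMethod("geneIds", "GenePanel", function(x) x@genes)

#' @describeIn GenePanel panel size.
#' @param x,object a \code{GenePanel}.
#' @export
setMethod("length", "GenePanel", function(x) length(x@genes))

setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel: %d genes (%d targets, %d cancer genes, %d both, %d padding)\n",
              length(object@genes),
              sum(object@provenance == "drug_target"),
              sum(object@provenance == "cancer_gene"),
              sum(object@provenance == "both"),
              sum(object@provenance == "padding")))
})

## CellFeatureMatrix ---------------------------------------------------------

#' CellFeatureMatrix: genes x cell-lines feature matrix with missingness
#'
#' @slot mat genes x cells numeric matrix (row order = gene panel order).
#' @slot featureKind \code{"expression"} or \code{"dependency"}.
#' @slot missingMask logical matrix marking entries that are (or were)
#'   missing; all FALSE after imputation.
#' @slot standardized logical flag; TRUE after per-gene z-scoring.
#' @slot degenerateGenes genes whose row had zero variance at
#'   standardization time (mapped to all-zero rows).
#' @exportClass CellFeatureMatrix
setClass("CellFeatureMatrix",
  representation(mat = "matrix", featureKind = "character",
                 missingMask = "matrix", standardized = "logical",
                 degenerateGenes = "character"))

setValidity("CellFeatureMatrix", function(object) {
  if (!object@featureKind %in% c("expression", "dependency"))
    return("featureKind must be 'expression' or 'dependency'")
  if (!identical(dim(object@mat), dim(object@missingMask)))
    return("missing mask dimension mismatch")
  if (is.null(rownames(object@mat))) return("matrix needs gene rownames")
  if (is.null(colnames(object@mat))) return("matrix needs cell-line colnames")
  TRUE
})

#' @rdname geneIds
#' @export
setMethod("geneIds", "CellFeatureMatrix", function(x) rownames(x@mat))

#' Cell-line identifiers
#' @param x a \code{CellFeatureMatrix}.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellIds
#' @export
setMethod("cellIds", "CellFeatureMatrix", function(x) colnames(x@mat))

#' Extract the numeric feature matrix
#' @param x a \code{CellFeatureMatrix} or \code{SampleTensor}.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "CellFeatureMatrix", function(x) x@mat)

setMethod("show", "CellFeatureMatrix", function(object) {
  cat(sprintf("CellFeatureMatrix (%s): %d genes x %d cells, %d missing%s\n",
              object@featureKind, nrow(object@mat), ncol(object@mat),
              sum(object@missingMask),
              if (object@standardized) ", standardized" else ""))
})

## SampleTensor --------------------------------------------------------------

#' SampleTensor: one model input sample (genes x feature columns)
#'
#' Columns are the two propagated drug profiles followed by one (single
#' mode) or two (dual mode) cell-line feature columns, all on the same
#' gene panel.
#'
#' @slot mat genes x k numeric matrix, k in \{3, 4\}.
#' @slot columnRoles ordered role tags, e.g.
#'   \code{c("drugA","drugB","cell_dependency")}.
#' @slot label numeric synergy score (NA when unlabelled).
#' @slot meta named list (drugA, drugB, cell identifiers).
#' @exportClass SampleTensor
setClass("SampleTensor",
  representation(mat = "matrix", columnRoles = "character",
                 label = "numeric", meta = "list"))

setValidity("SampleTensor", function(object) {
  k <- ncol(object@mat)
  if (!k %in% c(3L, 4L)) return("sample tensor must have 3 or 4 columns")
  if (length(object@columnRoles) != k) return("column role length mismatch")
  if (!identical(object@columnRoles[1:2], c("drugA", "drugB")))
    return("first two columns must be drugA, drugB")
  cellRoles <- object@columnRoles[-(1:2)]
  if (!all(cellRoles %in% c("cell_dependency", "cell_expression")))
    return("cell columns must be cell_dependency/cell_expression")
  TRUE
})

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SampleTensor", function(x) x@mat)

#' Column roles of a sample tensor
#' @param x a \code{SampleTensor}.
#' @export
setGeneric("columnRoles", function(x) standardGeneric("columnRoles"))

#' @rdname columnRoles
#' @export
setMethod("columnRoles", "SampleTensor", function(x) x@columnRoles)

setMethod("show", "SampleTensor", function(object) {
  cat(sprintf("SampleTensor: %d genes x %d columns (%s), label %s\n",
              nrow(object@mat), ncol(object@mat),
              paste(object@columnRoles, collapse = ", "),
              ifelse(is.na(object@label), "NA",
                     format(object@label, digits = 4))))
})
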