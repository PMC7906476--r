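## Molecular featurization: multi-hot atom/bond graphs with graph
## convolutional neural fingerprints, and classical descriptor vectors
## (circular fingerprint + physicochemical properties + toxicophores).
##
## SMILES handling is delegated to ChemmineR/ChemmineOB (OpenBabel).
## Molecules are canonicalized before featurization so the graph is a pure
## function of the molecule, not of the SMILES dialect it arrived in.

## Element vocabulary: 43 named symbols + "other" = 44 one-hot positions.
## Together with degree (0-5 -> 6), implicit hydrogen count (0-4 -> 5),
## formal charge (-2..+2 -> 5), aromatic flag (1) and ring flag (1) the
## atom feature width is 44+6+5+5+1+1 = 62. Bond features are bond order
## one-hot (single/double/triple/aromatic -> 4) + conjugated (1) +
## in-ring (1) = 6.
ELEMENT_VOCAB <- c(
  "C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si", "Se", "H",
  "Li", "Na", "K", "Mg", "Ca", "Fe", "Zn", "Cu", "Mn", "Co", "Ni", "Mo",
  "As", "Al", "Sn", "Ag", "Au", "Pt", "Pd", "Hg", "Pb", "Cr", "V", "Ti",
  "W", "Ba", "Sr", "Cd", "Sb", "Bi", "other")

ATOM_FEATURE_WIDTH <- 62L
BOND_FEATURE_WIDTH <- 6L

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1,
                      I = 1, P = 3, B = 3, Si = 4, Se = 2, H = 1)

#' MoleculeGraph: multi-hot featurized molecular graph
#'
#' @slot smiles canonical SMILES the graph was built from.
#' @slot elements atom element symbols (canonical atom order).
#' @slot atomFeatures n_atoms x 62 binary matrix.
#' @slot bondFeatures n_bonds x 6 binary matrix.
#' @slot bondIndex n_bonds x 2 integer matrix of atom indices.
#' @slot A n_atoms x n_atoms binary adjacency (symmetric, zero diagonal).
#' @exportClass MoleculeGraph
setClass("MoleculeGraph",
  representation(smiles = "character", elements = "character",
                 atomFeatures = "matrix", bondFeatures = "matrix",
                 bondIndex = "matrix", A = "matrix"))

setValidity("MoleculeGraph", function(object) {
  n <- length(object@elements)
  if (ncol(object@atomFeatures) != ATOM_FEATURE_WIDTH)
    return("atom feature width must be 62")
  if (ncol(object@bondFeatures) != BOND_FEATURE_WIDTH)
    return("bond feature width must be 6")
  if (nrow(object@atomFeatures) != n) return("atom feature row mismatch")
  if (!all(dim(object@A) == c(n, n))) return("adjacency dimension mismatch")
  if (any(diag(object@A) != 0)) return("adjacency diagonal must be zero")
  if (!isSymmetric(object@A)) return("adjacency must be symmetric")
  TRUE
})

#' @describeIn MoleculeGraph number of atoms.
#' @param x,object a \code{MoleculeGraph}.
#' @export
setMethod("length", "MoleculeGraph", function(x) length(x@elements))

#' @rdname adjacency
#' @export
setMethod("adjacency", "MoleculeGraph", function(x) x@A)

#' Atom feature matrix accessor
#' @param x a \code{MoleculeGraph}.
#' @export
setGeneric("atomFeatures", function(x) standardGeneric("atomFeatures"))

#' @rdname atomFeatures
#' @export
setMethod("atomFeatures", "MoleculeGraph", function(x) x@atomFeatures)

#' Bond feature matrix accessor
#' @param x a \code{MoleculeGraph}.
#' @export
setGeneric("bondFeatures", function(x) standardGeneric("bondFeatures"))

#' @rdname bondFeatures
#' @export
setMethod("bondFeatures", "MoleculeGraph", function(x) x@bondFeatures)

setMethod("show", "MoleculeGraph", function(object) {
  cat(sprintf("MoleculeGraph: %s (%d atoms, %d bonds)\n", object@smiles,
              length(object@elements), nrow(object@bondFeatures)))
})

oneHot <- function(value, levels) {
  v <- numeric(length(levels))
  idx <- match(value, levels)
  if (is.na(idx)) idx <- length(levels)   # clamp to last slot ("other"/max)
  v[idx] <- 1
  v
}

## SMILES -> single-molecule SDFset via OpenBabel conversion + SDF reader
## (more robust than the one-step helper, which misbehaves when the
## chemistry packages are not attached to the search path).
smilesToSdf <- function(smiles) {
  txt <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles)), silent = TRUE)
  if (inherits(txt, "try-error") || !nzchar(trimws(txt)))
    dsynetStop(paste("unparseable SMILES:", smiles), "dsynet_smiles_error",
               smiles = smiles)
  sdf <- try(suppressWarnings(
    ChemmineR::read.SDFset(strsplit(txt, "\n", fixed = TRUE)[[1]])),
    silent = TRUE)
  if (inherits(sdf, "try-error") || !ChemmineR::validSDF(sdf)[1])
    dsynetStop(paste("unparseable SMILES:", smiles), "dsynet_smiles_error",
               smiles = smiles)
  sdf
}

canonicalSmiles <- function(smiles) {
  out <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles)), silent = TRUE)
  if (inherits(out, "try-error") || !nzchar(trimws(out)))
    dsynetStop(paste("unparseable SMILES:", smiles), "dsynet_smiles_error",
               smiles = smiles)
  strsplit(trimws(out), "[[:space:]]")[[1]][1]
}

## Single atoms come straight from the canonical SMILES (OpenBabel's SDF
## for them trips ChemmineR), e.g. "C", "[NH4+]", "[Cl-]".
parseSingleAtom <- function(can) {
  m <- regmatches(can, regexec(
    "^\\[?([A-Z][a-z]?)(H([0-9]*))?(([+-])([0-9]*))?\\]?$", can))[[1]]
  if (length(m) == 0L) return(NULL)
  elem <- m[2]
  charge <- 0L
  if (nzchar(m[5])) {
    mag <- if (nzchar(m[7])) as.integer(m[7]) else 1L
    charge <- if (m[6] == "-") -mag else mag
  }
  nH <- if (nzchar(m[3])) {
    if (nzchar(m[4])) as.integer(m[4]) else 1L
  } else {
    val <- STANDARD_VALENCE[elem]
    if (is.na(val)) 0L else max(0L, as.integer(val) - abs(charge))
  }
  list(element = elem, charge = charge, nH = nH)
}

atomFeatureVector <- function(element, degree, nH, charge, aromatic, inRing) {
  c(oneHot(element, ELEMENT_VOCAB),
    oneHot(min(degree, 5L), 0:5),
    oneHot(min(nH, 4L), 0:4),
    oneHot(max(-2L, min(2L, charge)), -2:2),
    as.numeric(aromatic), as.numeric(inRing))
}

#' Featurize a molecule from its SMILES string
#'
#' Parses (and canonicalizes) the SMILES, then encodes every atom as a
#' 62-dimensional multi-hot vector (element identity over a 44-symbol
#' vocabulary, degree 0-5, implicit hydrogen count 0-4, formal charge
#' -2..+2, aromaticity, ring membership) and every bond as a 6-dimensional
#' vector (order single/double/triple/aromatic, conjugation, ring
#' membership).
#'
#' @param smiles a SMILES string.
#' @return a \code{\linkS4class{MoleculeGraph}}.
#' @examples
#' g <- featurizeMolecule("CCO")
#' dim(atomFeatures(g))
#' @export
featurizeMolecule <- function(smiles) {
  can <- canonicalSmiles(smiles)
  single <- parseSingleAtom(can)
  if (!is.null(single)) {
    af <- matrix(atomFeatureVector(single$element, 0L, single$nH,
                                   single$charge, FALSE, FALSE),
                 nrow = 1L)
    return(new("MoleculeGraph", smiles = can, elements = single$element,
               atomFeatures = af,
               bondFeatures = matrix(0, 0L, BOND_FEATURE_WIDTH),
               bondIndex = matrix(0L, 0L, 2L),
               A = matrix(0, 1L, 1L)))
  }
  sdf <- smilesToSdf(can)
  mol <- sdf[[1]]
  elems <- sub("_[0-9]+$", "", rownames(ChemmineR::atomblock(mol)))
  n <- length(elems)
  bb <- ChemmineR::bondblock(mol)
  bondIdx <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  order <- as.integer(bb[, 3])
  binfo <- ChemmineR::bonds(mol, type = "bonds")
  charges <- binfo$charge
  valence <- binfo$Nbondrule
  bondSum <- binfo$Nbondcount
  ## rings + aromaticity perception (kekulized SDF input)
  ringInfo <- ChemmineR::rings(mol, type = "all", arom = TRUE)
  ringAtoms <- integer(0)
  aromaticAtoms <- integer(0)
  ringBondKeys <- character(0)
  aromBondKeys <- character(0)
  bondKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  if (length(ringInfo$RINGS)) {
    for (ri in seq_along(ringInfo$RINGS)) {
      ids <- as.integer(sub("^.*_", "", ringInfo$RINGS[[ri]]))
      ringAtoms <- union(ringAtoms, ids)
      cyc <- bondKey(ids, c(ids[-1], ids[1]))
      ringBondKeys <- union(ringBondKeys, cyc)
      if (isTRUE(ringInfo$AROMATIC[ri])) {
        aromaticAtoms <- union(aromaticAtoms, ids)
        aromBondKeys <- union(aromBondKeys, cyc)
      }
    }
  }
  degree <- tabulate(c(bondIdx[, 1], bondIdx[, 2]), nbins = n)
  ## implicit hydrogens from standard valence, bond-order sum and charge
  hAdj <- ifelse(elems == "C", -abs(charges),
          ifelse(elems == "B", abs(charges), charges))
  nH <- pmax(0L, as.integer(round(valence - bondSum + hAdj)))
  af <- t(vapply(seq_len(n), function(i)
    atomFeatureVector(elems[i], degree[i], nH[i], charges[i],
                      i %in% aromaticAtoms, i %in% ringAtoms),
    numeric(ATOM_FEATURE_WIDTH)))
  ## bond features
  keys <- bondKey(bondIdx[, 1], bondIdx[, 2])
  isArom <- keys %in% aromBondKeys
  ## an atom is "unsaturated" if it carries a multiple or aromatic bond;
  ## a bond is conjugated when both of its atoms are unsaturated
  unsat <- logical(n)
  multi <- order >= 2 | isArom
  unsat[unique(c(bondIdx[multi, 1], bondIdx[multi, 2]))] <- TRUE
  bf <- t(vapply(seq_len(nrow(bondIdx)), function(b) {
    ord <- if (isArom[b]) 4L else min(order[b], 3L)
    c(oneHot(ord, 1:4),
      as.numeric(unsat[bondIdx[b, 1]] && unsat[bondIdx[b, 2]]),
      as.numeric(keys[b] %in% ringBondKeys))
  }, numeric(BOND_FEATURE_WIDTH)))
  if (nrow(bondIdx) == 0L) bf <- matrix(0, 0L, BOND_FEATURE_WIDTH)
  A <- matrix(0, n, n)
  A[bondIdx] <- 1
  A[bondIdx[, 2:1, drop = FALSE]] <- 1
  new("MoleculeGraph", smiles = can, elements = elems, atomFeatures = af,
      bondFeatures = bf, bondIndex = bondIdx, A = A)
}

#' One graph-convolution layer
#'
#' Computes \code{activation(D^-1 (A + I) H W)}: each atom averages itself
#' and its bonded neighbours, mixes channels through the learnable weight
#' matrix W, and applies the activation. The default activation is a
#' row-wise softmax (so every output row sums to 1); ReLU is available as
#' the conventional alternative.
#'
#' @param H n_atoms x in_dim node matrix.
#' @param graph a \code{\linkS4class{MoleculeGraph}}.
#' @param W in_dim x out_dim weight matrix.
#' @param activation \code{"softmax"} or \code{"relu"}.
#' @return n_atoms x out_dim node matrix.
#' @export
gcnLayer <- function(H, graph, W, activation = c("softmax", "relu")) {
  activation <- match.arg(activation)
  stopifnot(is(graph, "MoleculeGraph"))
  n <- length(graph@elements)
  H <- as.matrix(H)
  if (nrow(H) != n)
    dsynetStop("node matrix rows must equal the atom count",
               "dsynet_shape_error")
  if (ncol(H) != nrow(W))
    dsynetStop("H/W dimension mismatch", "dsynet_shape_error")
  AI <- graph@A + diag(n)
  Z <- (AI / rowSums(AI)) %*% H %*% W
  if (activation == "relu") return(pmax(Z, 0))
  ## row-wise softmax
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Graph-convolutional neural fingerprint of a molecule
#'
#' Applies a stack of \code{\link{gcnLayer}}s to the multi-hot atom
#' features, then concatenates the final per-atom representations in
#' canonical atom order, zero-padded to \code{maxAtoms} atoms, into a
#' single fixed-length vector.
#'
#' @param graph a \code{\linkS4class{MoleculeGraph}}.
#' @param layers list of weight matrices (first must have 62 input rows).
#' @param maxAtoms padding size; molecules with more atoms are rejected.
#' @param activation forwarded to \code{\link{gcnLayer}}.
#' @return numeric vector of length \code{maxAtoms * ncol(last layer)}.
#' @export
neuralFingerprint <- function(graph, layers, maxAtoms = 64L,
                              activation = "softmax") {
  stopifnot(is(graph, "MoleculeGraph"), length(layers) >= 1)
  n <- length(graph@elements)
  if (n > maxAtoms)
    dsynetStop(sprintf("molecule has %d atoms, exceeding maxAtoms = %d",
                       n, maxAtoms), "dsynet_input_error")
  H <- graph@atomFeatures
  for (W in layers) H <- gcnLayer(H, graph, W, activation)
  outDim <- ncol(H)
  out <- numeric(maxAtoms * outDim)
  out[seq_len(n * outDim)] <- as.numeric(t(H))  # atom-major layout
  out
}

#' Seeded random GCN weight stack for neural fingerprints
#'
#' @param dims integer vector of layer widths, e.g. \code{c(16, 8)}; the
#'   first layer consumes the 62 atom features.
#' @param seed integer RNG seed.
#' @return list of weight matrices usable with
#'   \code{\link{neuralFingerprint}}.
#' @export
gcnLayerStack <- function(dims = c(16L, 8L), seed = 1L) {
  set.seed(seed)
  inDim <- ATOM_FEATURE_WIDTH
  layers <- list()
  for (d in dims) {
    layers[[length(layers) + 1L]] <-
      matrix(stats::rnorm(inDim * d, sd = 1 / sqrt(inDim)), inDim, d)
    inDim <- d
  }
  layers
}

#' Classical chemical descriptor vector (fingerprint + physchem + toxicophores)
#'
#' Builds the descriptor representation used by the chemical-information
#' model variant: a circular (extended-connectivity, radius 2) fingerprint
#' folded to \code{fpBits} bits, a configurable physicochemical property
#' block, and a binary toxicophore block from SMARTS matches.
#'
#' @param smiles a SMILES string.
#' @param fpBits fingerprint length after folding (default 2048).
#' @param physchem character vector of property names to keep (subset of
#'   the OpenBabel property set: HBA1, HBA2, HBD, logP, MR, MW, nF, TPSA).
#' @param toxicophores data.frame with columns \code{name}, \code{smarts};
#'   default: the bundled toxicophore set
#'   (\code{system.file("extdata", "toxicophores.tsv", package = "dsynet")}).
#' @return named list with elements \code{fingerprint} (binary,
#'   \code{fpBits} long), \code{physchem} (named numeric), and
#'   \code{toxicophore} (named binary).
#' @export
chemDescriptors <- function(smiles, fpBits = 2048L,
                            physchem = c("HBA1", "HBA2", "HBD", "logP",
                                         "MR", "MW", "nF", "TPSA"),
                            toxicophores = NULL) {
  can <- canonicalSmiles(smiles)
  sdf <- smilesToSdf(can)
  fpRaw <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "ECFP4"))[1, ]
  nRaw <- length(fpRaw)
  fp <- integer(fpBits)
  idx <- ((seq_len(nRaw) - 1L) %% fpBits) + 1L   # fold by OR
  fp[idx] <- pmax(fp[idx], as.integer(fpRaw))
  props <- ChemmineR::propOB(sdf)
  pc <- vapply(physchem, function(p) as.numeric(props[[p]][1]), 0)
  if (is.null(toxicophores)) {
    path <- system.file("extdata", "toxicophores.tsv", package = "dsynet")
    toxicophores <- utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      comment.char = "")
  }
  tox <- vapply(seq_len(nrow(toxicophores)), function(i)
    as.integer(smartsMatches(can, toxicophores$smarts[i])), 0L)
  names(tox) <- toxicophores$name
  list(fingerprint = fp, physchem = pc, toxicophore = tox)
}

#' Flatten a chemDescriptors() result to one numeric vector
#' @param desc result of \code{\link{chemDescriptors}}.
#' @return numeric vector (fingerprint, physchem, toxicophore blocks).
#' @export
flattenDescriptors <- function(desc) {
  c(desc$fingerprint, unname(desc$physchem), unname(desc$toxicophore))
}

## SMARTS matching through the OpenBabel command-line filter.
smartsMatches <- function(smiles, smarts) {
  out <- suppressWarnings(system2("obabel",
    c(paste0("-:", shQuote(smiles)), "-osmi", "-s", shQuote(smarts)),
    stdout = TRUE, stderr = FALSE))
  any(nzchar(trimws(out)))
}

#' Read a drug_id<TAB>smiles table
#' @param path file path (optional header).
#' @return data.frame with columns \code{drug}, \code{smiles}.
#' @export
readSmilesFile <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (tolower(tab[1, 1]) %in% c("drug", "drug_id"))
    tab <- tab[-1, , drop = FALSE]
  data.frame(drug = tab[[1]], smiles = tab[[2]], stringsAsFactors = FALSE)
}
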