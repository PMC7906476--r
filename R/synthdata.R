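## Synthetic study generator. Emulates, at desk scale, the six inputs the
## full-scale study consumes: a weighted gene-gene interaction network, a
## binary drug-target table, cell-line dependency and expression matrices
## (with missingness), a synergy-score table, drug SMILES, plus GMT gene
## sets with a planted enrichment signal.
##
## The planted synergy mechanism couples propagated drug profiles to gene
## dependency: drugs whose network-propagated effect lands on genes a cell
## depends on are synergistic there. That is exactly the mechanistic
## premise the model encodes, so held-out recovery of the planted signal
## is a meaningful end-to-end test.

#' Synthetic study configuration
#'
#' Defaults are the package's declared desk-scale study conditions: a
#' 300-gene preferential-attachment interactome, 12 drugs with 3 targets
#' each, 8 cell lines, 5 percent missing feature entries, and a synergy
#' scale calibrated so roughly one record in eight exceeds the positive
#' threshold of 30.
#'
#' @param nGenes,nDrugs,nCells,targetsPerDrug,panelSize sizes.
#' @param edgeDensity preferential-attachment edges added per new gene.
#' @param noiseSd additive Gaussian noise on synergy scores (score units).
#' @param interactionWeight,mainEffectWeight weights c1 (drug-drug-cell
#'   interaction term) and c2 (per-drug main effects) of the planted
#'   mechanism.
#' @param exprDepCor target correlation between expression and dependency.
#' @param missingFraction fraction of feature entries masked missing.
#' @param positiveFraction calibration quantile: the synergy scale is set
#'   so this fraction of noise-free scores exceeds 30.
#' @param seed integer master seed; every generator derives its stream
#'   from it.
#' @return list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(nGenes = 300L, nDrugs = 12L, nCells = 8L,
                        targetsPerDrug = 3L, panelSize = nGenes,
                        edgeDensity = 2L, noiseSd = 5,
                        interactionWeight = 1, mainEffectWeight = 0.5,
                        exprDepCor = 0.6, missingFraction = 0.05,
                        positiveFraction = 0.125, seed = 1L) {
  if (any(c(nGenes, nDrugs, nCells, targetsPerDrug, panelSize) < 1))
    dsynetStop("sizes must be positive", "dsynet_config_error")
  if (noiseSd < 0) dsynetStop("noiseSd must be >= 0", "dsynet_config_error")
  structure(list(nGenes = as.integer(nGenes), nDrugs = as.integer(nDrugs),
                 nCells = as.integer(nCells),
                 targetsPerDrug = as.integer(targetsPerDrug),
                 panelSize = as.integer(panelSize),
                 edgeDensity = as.integer(edgeDensity), noiseSd = noiseSd,
                 interactionWeight = interactionWeight,
                 mainEffectWeight = mainEffectWeight,
                 exprDepCor = exprDepCor, missingFraction = missingFraction,
                 positiveFraction = positiveFraction,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

synthGeneIds <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a synthetic gene interaction network
#'
#' Connected preferential-attachment (scale-free-like) graph with edge
#' confidences drawn uniformly from the STRING-like range (0.15, 0.999).
#'
#' @param config a \code{\link{synthConfig}}.
#' @return a \code{\linkS4class{GeneNetwork}}.
#' @export
genNetwork <- function(config = synthConfig()) {
  set.seed(config$seed + 101L)
  g <- igraph::sample_pa(config$nGenes, m = config$edgeDensity,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- synthGeneIds(config$nGenes)
  edges <- data.frame(geneA = ids[el[, 1]], geneB = ids[el[, 2]],
                      confidence = stats::runif(nrow(el), 0.15, 0.999),
                      stringsAsFactors = FALSE)
  geneNetwork(edges, geneIds = ids)
}

#' Generate synthetic drugs: target table and SMILES
#'
#' Each drug receives \code{targetsPerDrug} distinct targets sampled
#' without replacement from the network genes (drugs may share targets),
#' and a parseable small-molecule SMILES from the bundled library.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param network the \code{\linkS4class{GeneNetwork}} to draw targets from.
#' @return list: \code{targets} (long data.frame drug/gene),
#'   \code{smiles} (data.frame drug/smiles).
#' @export
genDrugs <- function(config = synthConfig(), network = genNetwork(config)) {
  set.seed(config$seed + 202L)
  genes <- geneIds(network)
  drugs <- sprintf("D%02d", seq_len(config$nDrugs))
  targets <- do.call(rbind, lapply(drugs, function(d)
    data.frame(drug = d,
               gene = sample(genes, config$targetsPerDrug),
               stringsAsFactors = FALSE)))
  lib <- utils::read.table(
    system.file("extdata", "smiles_library.tsv", package = "dsynet"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  smiles <- data.frame(
    drug = drugs,
    smiles = lib$smiles[(seq_len(config$nDrugs) - 1L) %% nrow(lib) + 1L],
    stringsAsFactors = FALSE)
  list(targets = targets, smiles = smiles)
}

#' Generate synthetic cell-line dependency and expression matrices
#'
#' Dependency is a per-gene latent essentiality plus cell-specific noise
#' (standard-normal scale); expression is correlated with dependency at
#' the configured level, with a configured fraction of entries masked
#' missing in both matrices.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list of \code{\linkS4class{CellFeatureMatrix}}:
#'   \code{dependency}, \code{expression}, plus \code{latentDependency}
#'   (complete, unmasked matrix used by the synergy generator).
#' @export
genCells <- function(config = synthConfig()) {
  set.seed(config$seed + 303L)
  n <- config$nGenes; m <- config$nCells
  genes <- synthGeneIds(n)
  cells <- sprintf("CL%02d", seq_len(m))
  essent <- stats::rnorm(n, sd = sqrt(0.5))
  dep <- matrix(essent, n, m) + matrix(stats::rnorm(n * m, sd = sqrt(0.5)), n, m)
  rho <- config$exprDepCor
  expr <- rho * dep + sqrt(1 - rho^2) * matrix(stats::rnorm(n * m), n, m)
  dimnames(dep) <- dimnames(expr) <- list(genes, cells)
  mask <- function(mat) {
    if (config$missingFraction <= 0) return(mat)
    nMiss <- round(config$missingFraction * length(mat))
    ## never blank out a full row/column at these sizes; cap per row
    idx <- sample(length(mat), nMiss)
    mat[idx] <- NA
    ## repair rows left with < 2 observations
    bad <- which(rowSums(!is.na(mat)) < 2)
    for (b in bad) mat[b, 1:2] <- c(dep[b, 1], dep[b, 2])
    mat
  }
  list(dependency = cellFeatureMatrix(mask(dep), "dependency"),
       expression = cellFeatureMatrix(mask(expr), "expression"),
       latentDependency = dep)
}

#' Generate synergy scores with a planted mechanism
#'
#' For drugs A, B on cell c the noise-free score is
#' \code{s * (c1 * sum_g rA(g) rB(g) dep(g,c) + c2 * (sum_g rA(g) dep(g,c)
#' + sum_g rB(g) dep(g,c)))}, symmetric in A and B by construction. The
#' scale s is calibrated on the noise-free scores so that the configured
#' fraction of records exceeds the positive threshold 30 (keeping
#' classification metrics meaningful); Gaussian noise of sd
#' \code{noiseSd} is then added.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param profiles a \code{\linkS4class{DrugProfileSet}} of propagated
#'   drug profiles.
#' @param dependency complete genes x cells dependency matrix (the latent
#'   matrix from \code{\link{genCells}}).
#' @return normalized synergy record table covering every unordered drug
#'   pair x cell combination.
#' @export
genSynergy <- function(config, profiles, dependency) {
  drugs <- drugIds(profiles)
  cells <- colnames(dependency)
  R <- propagatedProfiles(profiles)[, rownames(dependency), drop = FALSE]
  combos <- expand.grid(a = seq_along(drugs), b = seq_along(drugs),
                        cell = seq_along(cells))
  combos <- combos[combos$a < combos$b, ]
  c1 <- config$interactionWeight; c2 <- config$mainEffectWeight
  main <- R %*% dependency                      # drugs x cells: <r, dep>
  raw <- vapply(seq_len(nrow(combos)), function(i) {
    a <- combos$a[i]; b <- combos$b[i]; cl <- combos$cell[i]
    inter <- sum(R[a, ] * R[b, ] * dependency[, cl])
    c1 * inter + c2 * (main[a, cl] + main[b, cl])
  }, 0)
  q <- stats::quantile(raw, 1 - config$positiveFraction, names = FALSE)
  s <- if (q > 0) 30 / q else 1
  set.seed(config$seed + 404L)
  score <- raw * s + stats::rnorm(length(raw), sd = config$noiseSd)
  synergyRecords(data.frame(
    drugA = drugs[combos$a], drugB = drugs[combos$b],
    cell = cells[combos$cell], score = score, stringsAsFactors = FALSE))
}

#' Generate gene sets with one planted enriched set
#'
#' The planted set contains the top-scoring genes of a designated score
#' vector (so it is, by construction, enriched at the top of any ranking
#' that recovers those scores); the remaining sets are random and
#' size-matched.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param plantedScores named numeric vector over the gene universe.
#' @param setSize members per set (default 15).
#' @param nSets total number of sets including the planted one.
#' @return named list of gene sets; the planted one is
#'   \code{"planted_top"}.
#' @export
genGeneSets <- function(config, plantedScores, setSize = 15L, nSets = 10L) {
  genes <- names(plantedScores)
  if (is.null(genes))
    dsynetStop("plantedScores must be named by gene", "dsynet_input_error")
  planted <- genes[order(plantedScores, decreasing = TRUE)][seq_len(setSize)]
  set.seed(config$seed + 505L)
  sets <- c(list(planted_top = planted),
            stats::setNames(lapply(seq_len(nSets - 1L), function(i)
              sample(genes, setSize)),
              sprintf("random_%02d", seq_len(nSets - 1L))))
  attr(sets, "descriptions") <- stats::setNames(
    c("planted top-attribution genes",
      rep("random size-matched set", nSets - 1L)), names(sets))
  sets
}

#' Generate a complete synthetic study and write its input files
#'
#' Runs every generator and writes the input files in the exact dialects
#' the package readers consume: \code{edges.tsv}, \code{targets.tsv},
#' \code{smiles.tsv}, \code{dependency.csv}, \code{expression.csv},
#' \code{synergy.csv}, \code{cancer_genes.txt} and
#' \code{gene_sets.gmt}.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param outDir output directory (created); NULL skips writing.
#' @param propagation a \code{\link{propagationConfig}} used to build the
#'   profiles behind the planted mechanism.
#' @return list with all in-memory objects (network, drugs, cells,
#'   profiles, records, geneSets, cancerGenes, dir).
#' @export
simulateStudy <- function(config = synthConfig(), outDir = NULL,
                          propagation = propagationConfig()) {
  network <- genNetwork(config)
  drugs <- genDrugs(config, network)
  cells <- genCells(config)
  profiles <- propagateDrugs(network, drugs$targets, propagation)
  records <- genSynergy(config, profiles, cells$latentDependency)
  set.seed(config$seed + 606L)
  cancerGenes <- sort(sample(geneIds(network),
                             min(config$nGenes, config$panelSize) %/% 2L))
  ## plant the enrichment where the mechanism puts signal: genes weighted
  ## by total propagated drug mass times mean |dependency|
  signal <- colSums(propagatedProfiles(profiles)) *
    rowMeans(abs(cells$latentDependency))
  geneSets <- genGeneSets(config, signal)
  out <- list(config = config, network = network, targets = drugs$targets,
              smiles = drugs$smiles, dependency = cells$dependency,
              expression = cells$expression,
              latentDependency = cells$latentDependency,
              profiles = profiles, records = records,
              cancerGenes = cancerGenes, geneSets = geneSets)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(f) file.path(outDir, f)
    utils::write.table(network@edges, w("edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(drugs$targets, w("targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(drugs$smiles, w("smiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeMatrixCsv <- function(fm, f) {
      m <- featureMatrix(fm)
      utils::write.csv(data.frame(gene = rownames(m), m,
                                  check.names = FALSE), f,
                       row.names = FALSE, quote = FALSE, na = "NA")
    }
    writeMatrixCsv(cells$dependency, w("dependency.csv"))
    writeMatrixCsv(cells$expression, w("expression.csv"))
    utils::write.csv(data.frame(drug_a = records$drugA,
                                drug_b = records$drugB,
                                cell_line = records$cell,
                                synergy = records$score),
                     w("synergy.csv"), row.names = FALSE, quote = FALSE)
    writeLines(cancerGenes, w("cancer_genes.txt"))
    writeGMT(geneSets, w("gene_sets.gmt"))
    out$dir <- outDir
  }
  out
}
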