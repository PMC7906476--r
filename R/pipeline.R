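## Unified pipeline surface: resolved run configuration, stage driver,
## manifests. The command-line entry point (inst/cli/dsynet.R) is a thin
## wrapper over runPipeline().

CONFIG_SCHEMA <- list(
  global = c("seed", "outDir", "logLevel"),
  inputs = c("edges", "targets", "smiles", "dependency", "expression",
             "synergy", "cancerGenes", "geneSets", "model"),
  synthdata = c("nGenes", "nDrugs", "nCells", "targetsPerDrug", "panelSize",
                "edgeDensity", "noiseSd", "interactionWeight",
                "mainEffectWeight", "exprDepCor", "missingFraction",
                "positiveFraction", "seed"),
  netprop = c("alpha", "tol", "maxIter", "solver", "normalizeSeed",
              "danglingPolicy"),
  features = c("panelSize", "allowPadding", "mode", "imputeMaxIter",
               "imputeTol"),
  model = c("reducedDim", "nHeads", "nLayers", "ffDim", "dropout",
            "headHidden", "variant", "extraDim", "lr", "batchSize",
            "epochs"),
  evalsplit = c("scenario", "nFolds", "foldIndices", "validationFraction",
                "threshold", "augment", "evalEvery"),
  sagsea = c("backgroundSummaryK", "nRepeats", "integrationSteps",
             "nPermutations", "weightP", "column", "sampleIndex"))

#' Load and validate a run configuration
#'
#' YAML (or JSON) file with sections \code{global}, \code{inputs},
#' \code{synthdata}, \code{netprop}, \code{features}, \code{model},
#' \code{evalsplit}, \code{sagsea}, each mirroring the corresponding
#' module's configuration fields. Unknown sections or keys are rejected
#' with the offending name.
#'
#' @param path config file path, or a named list already in memory.
#' @return validated nested list of class \code{"RunConfig"}.
#' @export
loadRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  badSection <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(badSection))
    dsynetStop(paste("unknown config section:", badSection[1]),
               "dsynet_config_error")
  for (sec in names(cfg)) {
    badKey <- setdiff(names(cfg[[sec]]), CONFIG_SCHEMA[[sec]])
    if (length(badKey))
      dsynetStop(sprintf("unknown key '%s' in config section '%s'",
                         badKey[1], sec), "dsynet_config_error")
  }
  defaults <- list(global = list(seed = 1L, outDir = "dsynet_out",
                                 logLevel = "info"))
  for (sec in names(defaults))
    for (k in names(defaults[[sec]]))
      if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- defaults[[sec]][[k]]
  structure(cfg, class = "RunConfig")
}

writeManifest <- function(outDir, config, inputFiles = character()) {
  existing <- inputFiles[file.exists(inputFiles)]
  manifest <- list(
    package = "dsynet",
    version = as.character(utils::packageVersion("dsynet")),
    rVersion = R.version.string,
    seed = config$global$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    inputs = as.list(stats::setNames(
      as.character(tools::md5sum(existing)), existing)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(outDir, "resolved_config.yaml"))
  invisible(manifest)
}

## Read every study input named in config$inputs and assemble panel,
## profiles and standardized features.
prepareStudyInputs <- function(config) {
  ins <- config$inputs
  need <- c("edges", "targets", "synergy")
  miss <- need[!vapply(need, function(k) !is.null(ins[[k]]), TRUE)]
  if (length(miss))
    dsynetStop(paste("config inputs missing:", paste(miss, collapse = ", ")),
               "dsynet_config_error")
  network <- readEdgeList(ins$edges)
  targets <- readTargetTable(ins$targets)
  records <- readSynergyTable(ins$synergy)
  cancerGenes <- if (!is.null(ins$cancerGenes)) readGeneList(ins$cancerGenes)
                 else character()
  fc <- config$features
  panelSize <- fc$panelSize
  if (is.null(panelSize))
    panelSize <- length(union(unique(targets$gene), cancerGenes))
  allowPadding <- isTRUE(fc$allowPadding)
  panel <- selectGenePanel(targets, cancerGenes, panelSize = panelSize,
                           allowPadding = allowPadding)
  ## restrict the network to the panel so drug and cell features share it
  keep <- network@edges$geneA %in% geneIds(panel) &
          network@edges$geneB %in% geneIds(panel)
  network <- geneNetwork(network@edges[keep, ], geneIds = geneIds(panel))
  npc <- config$netprop
  prop <- propagationConfig(
    alpha = npc$alpha %||% 0.5, tol = npc$tol %||% 1e-8,
    maxIter = npc$maxIter %||% 1000L, solver = npc$solver %||% "direct",
    normalizeSeed = npc$normalizeSeed %||% TRUE)
  profiles <- propagateDrugs(network, targets, prop,
                             danglingPolicy = npc$danglingPolicy %||% "self_loop")
  ## align profiles to the full panel (padding genes get zero columns)
  profFull <- matrix(0, length(drugIds(profiles)), length(panel),
                     dimnames = list(drugIds(profiles), geneIds(panel)))
  profFull[, geneIds(profiles)] <- propagatedProfiles(profiles)
  seedFull <- matrix(0, length(drugIds(profiles)), length(panel),
                     dimnames = list(drugIds(profiles), geneIds(panel)))
  seedFull[, geneIds(profiles)] <- seedProfiles(profiles)
  profiles <- new("DrugProfileSet", drugIds = drugIds(profiles),
                  geneIds = geneIds(panel), seeds = seedFull,
                  propagated = profFull, rejects = profiles@rejects)
  mode <- fc$mode %||% "dependency"
  loadFeat <- function(key, kind) {
    if (is.null(ins[[key]])) return(NULL)
    fm <- readFeatureMatrix(ins[[key]], featureKind = kind, panel = panel)
    fm <- imputeMissing(fm, maxIter = fc$imputeMaxIter %||% 10L,
                        tol = fc$imputeTol %||% 1e-4)
    standardizeFeatures(fm)
  }
  dependency <- if (mode %in% c("dependency", "dual"))
    loadFeat("dependency", "dependency") else NULL
  expression <- if (mode %in% c("expression", "dual"))
    loadFeat("expression", "expression") else NULL
  if (is.null(dependency) && is.null(expression))
    dsynetStop("no cell feature matrix configured", "dsynet_config_error")
  ## drop records whose drugs/cells have no inputs
  fm <- if (!is.null(dependency)) dependency else expression
  ok <- records$drugA %in% drugIds(profiles) &
        records$drugB %in% drugIds(profiles) &
        records$cell %in% cellIds(fm)
  records <- synergyRecords(records[ok, c("drugA", "drugB", "cell", "score")])
  list(panel = panel, network = network, profiles = profiles,
       dependency = dependency, expression = expression, records = records,
       nTokens = 2L + (!is.null(dependency)) + (!is.null(expression)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

buildModelConfig <- function(config, panelSize, nTokens, seed) {
  mc <- config$model
  modelConfig(panelSize = panelSize,
              reducedDim = mc$reducedDim %||% 512L,
              nHeads = mc$nHeads %||% 8L, nLayers = mc$nLayers %||% 1L,
              ffDim = mc$ffDim %||% 512L, dropout = mc$dropout %||% 0.2,
              headHidden = unlist(mc$headHidden) %||% c(2048L, 512L),
              variant = mc$variant %||% "base",
              extraDim = mc$extraDim %||% 0L, nTokens = nTokens,
              seed = seed, lr = mc$lr %||% 1e-4,
              batchSize = mc$batchSize %||% 64L,
              epochs = mc$epochs %||% 100L)
}

buildSplitPlan <- function(config, study, seed) {
  ec <- config$evalsplit
  scenario <- ec$scenario %||% "leave_combination"
  vf <- ec$validationFraction %||% 0.2
  switch(scenario,
    leave_combination = splitLeaveCombinationOut(
      study$records, nFolds = ec$nFolds %||% 5L, seed = seed),
    leave_cell = {
      fm <- study$dependency %||% study$expression
      splitLeaveCellOut(study$records, t(featureMatrix(fm)),
                        validationFraction = vf, seed = seed)
    },
    leave_drug = {
      fps <- t(vapply(drugIds(study$profiles), function(d)
        propagatedProfiles(study$profiles)[d, ],
        numeric(length(study$panel))))
      splitLeaveDrugOut(study$records, fps, validationFraction = vf,
                        seed = seed)
    },
    dsynetStop(paste("unknown scenario", scenario), "dsynet_config_error"))
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write a synthetic study),
#' \code{propagate} (network propagation of drug targets),
#' \code{train} (split, train, test metrics, checkpoint),
#' \code{evaluate} (metrics of a saved model on the full record table),
#' \code{predict} (z-score-ranked novel pair table) and \code{explain}
#' (SA-GSEA attribution report for a chosen record). Every stage writes
#' its artifacts plus a manifest (input hashes, seed, versions) and the
#' resolved configuration into the output directory.
#'
#' @param config path to a YAML config file, or a config list; see
#'   \code{\link{loadRunConfig}}.
#' @param stage one of simulate, propagate, train, evaluate, predict,
#'   explain.
#' @param seed optional override of the global seed.
#' @param outDir optional override of the output directory.
#' @return invisibly, a list of the stage's main in-memory results.
#' @export
runPipeline <- function(config, stage = c("simulate", "propagate", "train",
                                          "evaluate", "predict", "explain"),
                        seed = NULL, outDir = NULL) {
  stage <- match.arg(stage)
  config <- loadRunConfig(config)
  if (!is.null(seed)) config$global$seed <- as.integer(seed)
  if (!is.null(outDir)) config$global$outDir <- outDir
  out <- config$global$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seedVal <- as.integer(config$global$seed)
  inputFiles <- unlist(config$inputs, use.names = FALSE)
  result <- switch(stage,
    simulate = {
      sc <- config$synthdata
      sc$seed <- sc$seed %||% seedVal
      study <- simulateStudy(do.call(synthConfig, sc), outDir = out)
      list(study = study)
    },
    propagate = {
      ins <- config$inputs
      if (is.null(ins$edges) || is.null(ins$targets))
        dsynetStop("propagate needs inputs: edges, targets",
                   "dsynet_config_error")
      network <- readEdgeList(ins$edges)
      targets <- readTargetTable(ins$targets)
      npc <- config$netprop
      prop <- propagationConfig(
        alpha = npc$alpha %||% 0.5, tol = npc$tol %||% 1e-8,
        maxIter = npc$maxIter %||% 1000L,
        solver = npc$solver %||% "direct")
      profiles <- propagateDrugs(network, targets, prop)
      writeProfiles(profiles, file.path(out, "propagated_profiles.tsv"))
      if (length(profiles@rejects))
        writeLines(profiles@rejects, file.path(out, "rejected_drugs.txt"))
      list(profiles = profiles)
    },
    train = {
      study <- prepareStudyInputs(config)
      plan <- buildSplitPlan(config, study, seedVal)
      writeSplitPlan(plan, file.path(out, "split_plan.json"))
      mcfg <- buildModelConfig(config, length(study$panel), study$nTokens,
                               seedVal)
      ec <- config$evalsplit
      folds <- ec$foldIndices %||% 1L
      fit <- trainSynergyModel(study$records, plan, study$profiles,
                               study$dependency, study$expression,
                               config = mcfg,
                               foldIndices = as.integer(unlist(folds)),
                               augment = ec$augment %||% TRUE,
                               evalEvery = ec$evalEvery %||% 10L)
      writeModel(fit$folds[[1]]$model, file.path(out, "model.rds"))
      if (!is.null(fit$metrics))
        utils::write.csv(fit$metrics, file.path(out, "test_metrics.csv"),
                         row.names = FALSE)
      list(fit = fit, plan = plan, study = study)
    },
    evaluate = {
      study <- prepareStudyInputs(config)
      model <- readModel(config$inputs$model %||% file.path(out, "model.rds"))
      samples <- buildSampleSet(study$records, study$profiles,
                                study$dependency, study$expression)
      pred <- predictSynergy(model, samples)
      m <- computeMetrics(study$records$score, pred,
                          threshold = config$evalsplit$threshold %||% 30)
      jsonlite::write_json(m, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      list(metrics = m, predictions = pred)
    },
    predict = {
      study <- prepareStudyInputs(config)
      model <- readModel(config$inputs$model %||% file.path(out, "model.rds"))
      ranked <- predictNovelPairs(model, study$records, study$profiles,
                                  study$dependency, study$expression)
      utils::write.table(ranked, file.path(out, "novel_pairs_ranked.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(ranked = ranked)
    },
    explain = {
      study <- prepareStudyInputs(config)
      model <- readModel(config$inputs$model %||% file.path(out, "model.rds"))
      sg <- config$sagsea
      samples <- buildSampleSet(study$records, study$profiles,
                                study$dependency, study$expression)
      idx <- sg$sampleIndex %||% which.max(study$records$score)
      bg <- backgroundCentroids(samples, k = sg$backgroundSummaryK %||% 25L,
                                seed = seedVal)
      acfg <- attributionConfig(
        backgroundSummaryK = sg$backgroundSummaryK %||% 25L,
        nRepeats = sg$nRepeats %||% 10L,
        integrationSteps = sg$integrationSteps %||% 128L, seed = seedVal)
      report <- computeAttributions(model, samples[[idx]], bg, acfg)
      utils::write.table(
        data.frame(gene = rownames(attributions(report)),
                   attributions(report), check.names = FALSE),
        file.path(out, "attributions.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      enr <- NULL
      if (!is.null(config$inputs$geneSets)) {
        sets <- readGMT(config$inputs$geneSets)
        enr <- saGsea(report, sets, column = sg$column %||% NULL,
                      nPermutations = sg$nPermutations %||% 1000L,
                      seed = seedVal, weightP = sg$weightP %||% 1)
        utils::write.table(enr, file.path(out, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ## JSON summary: explained record, top drug-target attributions,
        ## most enriched set
        rec <- study$records[idx, ]
        tgtA <- rankGenes(report, "drugA")
        tgtB <- rankGenes(report, "drugB")
        jsonlite::write_json(list(
          drugA = rec$drugA, drugB = rec$drugB, cell = rec$cell,
          observedScore = rec$score, predictedScore = report@modelOutput,
          topTargetsDrugA = utils::head(tgtA$gene, 5),
          topTargetsDrugB = utils::head(tgtB$gene, 5),
          mostEnrichedSet = enr$geneSet[1], enrichmentP = enr$p[1]),
          file.path(out, "explanation_summary.json"), auto_unbox = TRUE)
      }
      list(report = report, enrichment = enr)
    })
  writeManifest(out, config, inputFiles)
  invisible(result)
}
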