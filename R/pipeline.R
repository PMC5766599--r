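#' @include simulate.R io.R nbglm.R confirm.R qpcr.R enrichment.R network.R
NULL

#' Assemble and validate a pipeline configuration
#'
#' Collects every knob of the end-to-end run: thresholds (discovery FDR
#' 0.2, confirmation FDR 0.05, edge fraction 0.005, stagewise alpha 0.05),
#' the seed every random draw flows from, the output directory, and either
#' a synthetic-simulation block or paths to user-supplied inputs.
#'
#' @param outputDir directory the run writes into (created if absent)
#' @param seed integer master seed
#' @param simulation named list of [simulationConfig()] arguments
#'   (synthetic mode); ignored when `inputs` is given
#' @param qpcr named list of [simulateQpcrCohort()] arguments (synthetic
#'   mode)
#' @param inputs optional named list of file paths: `counts_discovery`,
#'   `samples_discovery`, `counts_confirmation`, `samples_confirmation`,
#'   `annotation`, and optionally `qpcr_table`, `gene_sets`, `set_id`,
#'   `target`, `known_lncrnas`
#' @param fdrDisc,fdrConf,edgeFraction,alpha analysis thresholds
#' @param minExpressedSamples low-count filter for the DE stages
#' @return A validated list of class `lncPipelineConfig`.
#' @examples
#' pipelineConfig(tempfile(), seed = 1,
#'                simulation = list(nFeatures = 100, nTumorConfirm = 30,
#'                                  nNormalConfirm = 10))
#' @export
pipelineConfig <- function(outputDir, seed = 1L, simulation = list(),
                           qpcr = list(), inputs = NULL, fdrDisc = 0.2,
                           fdrConf = 0.05, edgeFraction = 0.005,
                           alpha = 0.05, minExpressedSamples = 2L) {
  if (fdrDisc <= 0 || fdrDisc >= 1) stop("fdrDisc must lie in (0, 1)")
  if (fdrConf <= 0 || fdrConf >= 1) stop("fdrConf must lie in (0, 1)")
  if (edgeFraction <= 0 || edgeFraction > 0.5)
    stop("edgeFraction must lie in (0, 0.5]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(inputs)) {
    need <- c("counts_discovery", "samples_discovery",
              "counts_confirmation", "samples_confirmation", "annotation")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("inputs is missing: ", paste(miss, collapse = ", "))
    absent <- setdiff(names(inputs), c("set_id", "target"))
    absent <- absent[!vapply(inputs[absent],
                             function(p) file.exists(as.character(p)),
                             logical(1))]
    if (length(absent))
      stop("input file(s) not found: ",
           paste(unlist(inputs[absent]), collapse = ", "))
  }
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 simulation = simulation, qpcr = qpcr, inputs = inputs,
                 fdrDisc = fdrDisc, fdrConf = fdrConf,
                 edgeFraction = edgeFraction, alpha = alpha,
                 minExpressedSamples = as.integer(minExpressedSamples)),
            class = "lncPipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Loads a YAML file whose top-level keys are the arguments of
#' [pipelineConfig()] and returns the validated configuration. Arguments
#' passed through `...` override values from the file.
#'
#' @param path YAML file
#' @param ... overrides, e.g. `seed = 7`
#' @return A validated configuration (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipelineConfig, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full discovery-to-network pipeline
#'
#' Executes, in order: cohort simulation (or input loading), paired
#' discovery DE, unpaired confirmation DE, dual-cohort confirmation with
#' direction partition and novelty annotation, qPCR paired and stagewise
#' statistics, correlation-rank enrichment of the planted (or configured)
#' gene set against the target lncRNA, and co-expression network
#' construction with a hub report. Every intermediate artifact is written
#' as TSV (plus SIF/GraphML for the network) under `outputDir`, and a
#' manifest with parameters, per-stage row counts and MD5 checksums of
#' every output is written as `manifest.json`. Runs with the same
#' configuration and seed are bit-identical.
#'
#' @param cfg configuration from [pipelineConfig()] or
#'   [readPipelineConfig()]
#' @return The manifest, invisibly (a list).
#' @examples
#' cfg <- pipelineConfig(file.path(tempdir(), "demo"), seed = 1,
#'                       simulation = list(nFeatures = 150, nTrueDE = 12,
#'                                         nTumorConfirm = 40,
#'                                         nNormalConfirm = 12),
#'                       qpcr = list(nPairs = 20))
#' mf <- runPipeline(cfg)
#' mf$counts$confirmed_hits
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "lncPipelineConfig"))
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outputDir, f)
  synthetic <- is.null(cfg$inputs)
  message("run: ", if (synthetic) "synthetic mode" else "file-input mode",
          "; seed = ", cfg$seed,
          "; fdrDisc = ", cfg$fdrDisc, "; fdrConf = ", cfg$fdrConf,
          "; edgeFraction = ", cfg$edgeFraction,
          "; alpha = ", cfg$alpha,
          "; minExpressedSamples = ", cfg$minExpressedSamples)

  ## ---- stage: inputs -------------------------------------------------
  truth <- NULL
  if (synthetic) {
    simArgs <- cfg$simulation
    simArgs$seed <- cfg$seed
    simCfg <- .stage("simulate", do.call(simulationConfig, simArgs))
    disc <- .stage("simulate", simulateDiscoveryCohort(simCfg))
    confSe <- .stage("simulate",
                     simulateConfirmationCohort(simCfg, disc$truth))
    discSe <- disc$experiment
    truth <- disc$truth
    qArgs <- cfg$qpcr
    if (is.null(qArgs$nPairs)) qArgs$nPairs <- 139L
    qArgs$seed <- cfg$seed + 2L
    qpcrTab <- .stage("simulate", do.call(simulateQpcrCohort, qArgs))
    annotation <- featureAnnotation(discSe)
    target <- truth$feature_id[truth$is_target][1]
    geneSets <- list(PLANTED = truth$feature_id[truth$in_planted_set])
    setId <- "PLANTED"
    known <- character()
    .stage("simulate", {
      writeCounts(discSe, out("counts_discovery.tsv"))
      writeSampleSheet(sampleSheet(discSe), out("samples_discovery.tsv"))
      writeCounts(confSe, out("counts_confirmation.tsv"))
      writeSampleSheet(sampleSheet(confSe), out("samples_confirmation.tsv"))
      writeAnnotation(annotation, out("annotation.tsv"))
      writeGeneSets(geneSets, out("gene_sets.tsv"))
      writeTruth(truth, out("truth.tsv"))
      .writeTsv(qpcrTab, out("qpcr_table.tsv"))
    })
  } else {
    inp <- cfg$inputs
    discCounts <- .stage("load", readCounts(inp$counts_discovery))
    discSheet <- .stage("load", readSampleSheet(inp$samples_discovery,
                                                discCounts, paired = TRUE))
    confCounts <- .stage("load", readCounts(inp$counts_confirmation))
    confSheet <- .stage("load", readSampleSheet(inp$samples_confirmation,
                                                confCounts))
    annotation <- .stage("load", readAnnotation(inp$annotation))
    discSe <- .stage("load",
                     LncCountExperiment(discCounts, discSheet, annotation))
    confSe <- .stage("load",
                     LncCountExperiment(confCounts, confSheet, annotation))
    qpcrTab <- if (!is.null(inp$qpcr_table))
      .stage("load", .readTsv(inp$qpcr_table)) else NULL
    geneSets <- if (!is.null(inp$gene_sets))
      .stage("load", readGeneSets(inp$gene_sets)) else NULL
    setId <- inp$set_id
    target <- inp$target
    known <- if (!is.null(inp$known_lncrnas))
      .stage("load", readIdList(inp$known_lncrnas)) else character()
  }

  ## ---- stage: differential expression --------------------------------
  deDisc <- .stage("de_discovery",
                   pairedLRT(discSe, fdr = cfg$fdrDisc,
                             minExpressedSamples = cfg$minExpressedSamples))
  .stage("de_discovery", writeDEResults(deDisc, out("de_discovery.tsv")))
  deConf <- .stage("de_confirmation",
                   groupLRT(confSe, fdr = cfg$fdrConf,
                            minExpressedSamples = cfg$minExpressedSamples))
  .stage("de_confirmation",
         writeDEResults(deConf, out("de_confirmation.tsv")))

  ## ---- stage: confirmation accounting --------------------------------
  hits <- .stage("confirm",
                 confirmHits(deDisc, deConf, fdrDisc = cfg$fdrDisc,
                             fdrConf = cfg$fdrConf,
                             annotation = annotation))
  hits <- .stage("confirm", annotateNovelty(hits, known))
  parts <- .stage("confirm", partitionByDirection(hits))
  .stage("confirm", .writeTsv(hits, out("confirmed.tsv")))

  ## ---- stage: qPCR statistics ----------------------------------------
  qpcrPaired <- qpcrStagewise <- NULL
  if (!is.null(qpcrTab)) {
    rec <- .stage("qpcr", qpcrRecords(qpcrTab))
    qpcrPaired <- .stage("qpcr", qpcrPairedTest(rec))
    qpcrStagewise <- .stage("qpcr", stagewiseAnalysis(rec, cfg$alpha))
    .stage("qpcr", .writeTsv(qpcrPaired, out("qpcr_paired.tsv")))
  }

  ## ---- stage: enrichment ---------------------------------------------
  enrich <- NULL
  if (!is.null(target) && !is.null(geneSets) && length(setId) &&
        setId %in% names(geneSets)) {
    ranking <- .stage("enrich", correlateTargetVsAll(confSe, target))
    enrich <- .stage("enrich",
                     rankSetEnrichment(ranking, geneSets[[setId]], setId))
    .stage("enrich", .writeTsv(enrich, out("enrichment.tsv")))
  }

  ## ---- stage: network ------------------------------------------------
  verts <- .stage("network",
                  selectVertices(deDisc, deConf, annotation,
                                 fdrConf = cfg$fdrConf,
                                 fdrDisc = cfg$fdrDisc))
  net <- .stage("network",
                buildNetwork(confSe, verts,
                             edgeFraction = cfg$edgeFraction))
  hubs <- .stage("network", hubReport(net))
  .stage("network", {
    writeEdgeList(net, out("network_edges.tsv"))
    writeSif(net, out("network.sif"))
    writeGraphML(net, out("network.graphml"))
    .writeTsv(hubs, out("network_hubs.tsv"))
  })

  ## ---- manifest ------------------------------------------------------
  files <- sort(list.files(cfg$outputDir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(cfg$outputDir, files))
  manifest <- list(
    package_version = as.character(packageVersion("lncDiscoveR")),
    seed = cfg$seed,
    parameters = cfg[c("fdrDisc", "fdrConf", "edgeFraction", "alpha",
                       "minExpressedSamples")],
    mode = if (synthetic) "synthetic" else "files",
    counts = list(
      features = nrow(discSe),
      tested_discovery = sum(deResults(deDisc)$tested),
      tested_confirmation = sum(deResults(deConf)$tested),
      confirmed_hits = nrow(hits),
      up = nrow(parts$up), down = nrow(parts$down),
      novel = sum(hits$novel),
      network_vertices = nrow(networkVertices(net)),
      network_edges = nrow(networkEdges(net))),
    dispersion = list(discovery = dispersionEstimate(deDisc),
                      confirmation = dispersionEstimate(deConf)),
    enrichment_p = if (!is.null(enrich)) enrich$p_one_sided else NULL,
    qpcr = if (!is.null(qpcrPaired))
      list(p_value = qpcrPaired$p_value[1]) else NULL,
    outputs = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
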