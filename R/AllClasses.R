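#' @include lncDiscoveR-package.R
NULL

## Controlled vocabularies shared by validity methods and readers.
.CONDITIONS <- c("normal", "tumor")
.STAGES <- c("CA", "I", "II", "III", "IV")
.BIOTYPES <- c("lincRNA", "antisense", "retained_intron", "sense_intronic",
               "protein_coding", "other")

#' Simulation configuration for the synthetic cohorts
#'
#' Holds every parameter of the synthetic-data generator: the shape of the
#' matched discovery cohort and of the unpaired confirmation cohort, the
#' negative-binomial noise model (variance \eqn{\mu + \phi\mu^2}), the
#' planted differential-expression signal, and the latent co-expression
#' factor linking the target lncRNA to a planted gene set.
#'
#' @slot nPairsDiscovery number of matched tumor/normal pairs (default 3)
#' @slot nTumorConfirm tumor samples in the confirmation cohort (default 682)
#' @slot nNormalConfirm normal samples in the confirmation cohort (default 41)
#' @slot nFeatures total number of features simulated
#' @slot fracLncRNA fraction of features flagged as lncRNA, in \[0, 1\]
#' @slot nTrueDE number of features with a planted log2 fold change
#' @slot logfcRange interval (log2 scale) the planted |log2FC| is drawn from
#' @slot lncMeanCount baseline mean count of lncRNA features (low abundance)
#' @slot pcgMeanCount baseline mean count of protein-coding features
#' @slot dispersion NB dispersion \eqn{\phi}
#' @slot patientEffectSd SD of the per-patient log-scale random effect
#' @slot latentFactorLoading loading of the shared latent co-expression factor
#' @slot plantedSetSize number of protein-coding genes in the planted set
#' @slot libsizeVariation simulate log-normal per-sample depth factors?
#' @slot seed integer seed; every draw flows from it
#'
#' @seealso [simulationConfig()], [simulateDiscoveryCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nPairsDiscovery = "integer",
    nTumorConfirm = "integer",
    nNormalConfirm = "integer",
    nFeatures = "integer",
    fracLncRNA = "numeric",
    nTrueDE = "integer",
    logfcRange = "numeric",
    lncMeanCount = "numeric",
    pcgMeanCount = "numeric",
    dispersion = "numeric",
    patientEffectSd = "numeric",
    latentFactorLoading = "numeric",
    plantedSetSize = "integer",
    libsizeVariation = "logical",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  chk <- function(cond, field, why) if (!cond) sprintf("%s: %s", field, why)
  msgs <- c(
    chk(object@nPairsDiscovery >= 1L, "nPairsDiscovery", "must be >= 1"),
    chk(object@nTumorConfirm >= 2L, "nTumorConfirm", "must be >= 2"),
    chk(object@nNormalConfirm >= 2L, "nNormalConfirm", "must be >= 2"),
    chk(object@nFeatures >= 1L, "nFeatures", "must be >= 1"),
    chk(object@fracLncRNA >= 0 && object@fracLncRNA <= 1,
        "fracLncRNA", "must lie in [0, 1]"),
    chk(object@nTrueDE >= 0L && object@nTrueDE <= object@nFeatures,
        "nTrueDE", "must lie in [0, nFeatures]"),
    chk(length(object@logfcRange) == 2L && all(is.finite(object@logfcRange)) &&
          object@logfcRange[1] <= object@logfcRange[2],
        "logfcRange", "must be a finite non-decreasing interval"),
    chk(object@lncMeanCount > 0, "lncMeanCount", "must be positive"),
    chk(object@pcgMeanCount > 0, "pcgMeanCount", "must be positive"),
    chk(object@dispersion >= 0, "dispersion", "must be nonnegative"),
    chk(object@patientEffectSd >= 0, "patientEffectSd", "must be nonnegative"),
    chk(is.finite(object@latentFactorLoading),
        "latentFactorLoading", "must be finite"),
    chk(object@plantedSetSize >= 1L, "plantedSetSize", "must be >= 1")
  )
  msgs <- msgs[!vapply(msgs, is.null, logical(1))]
  if (length(msgs)) unlist(msgs) else TRUE
})

#' Count experiment for a tumor/normal lncRNA study
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `counts`
#' assay of nonnegative integers, sample metadata (`patient_id`, `condition`
#' in tumor/normal, `stage`) in `colData`, and feature metadata (`symbol`,
#' `biotype`, `is_lncRNA`) in `rowData`. The validity method enforces the
#' controlled vocabularies and unique feature/sample identifiers.
#'
#' @seealso [LncCountExperiment()], [sampleSheet()], [featureAnnotation()]
#' @export
setClass("LncCountExperiment", contains = "SummarizedExperiment")

setValidity("LncCountExperiment", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0))
      msgs <- c(msgs, "counts must be nonnegative and non-missing")
    else if (max(abs(cnt - round(cnt))) > 1e-8)
      msgs <- c(msgs, "counts must be integral")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids must be present and unique")
  cd <- colData(object)
  for (col in c("patient_id", "condition", "stage"))
    if (!col %in% colnames(cd))
      msgs <- c(msgs, sprintf("colData column '%s' is required", col))
  if ("condition" %in% colnames(cd) &&
      !all(cd$condition %in% .CONDITIONS))
    msgs <- c(msgs, sprintf("condition must be one of: %s",
                            paste(.CONDITIONS, collapse = ", ")))
  if ("stage" %in% colnames(cd) &&
      !all(cd$stage %in% .STAGES | is.na(cd$stage)))
    msgs <- c(msgs, sprintf("stage must be NA or one of: %s",
                            paste(.STAGES, collapse = ", ")))
  rd <- rowData(object)
  for (col in c("symbol", "biotype", "is_lncRNA"))
    if (!col %in% colnames(rd))
      msgs <- c(msgs, sprintf("rowData column '%s' is required", col))
  if ("biotype" %in% colnames(rd) && !all(rd$biotype %in% .BIOTYPES))
    msgs <- c(msgs, sprintf("biotype must be one of: %s",
                            paste(.BIOTYPES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Differential-expression result set
#'
#' Per-feature results of the negative-binomial GLM likelihood-ratio test:
#' log2 fold change (tumor vs normal), LRT statistic, p-value, BH-adjusted
#' FDR and direction, together with the normalization factors, the common
#' dispersion estimate and the analysis parameters used.
#'
#' @slot results `data.frame` with columns `feature_id`, `log2FC`,
#'   `lrt_stat`, `p_value`, `fdr`, `direction`, `tested`
#' @slot normFactors `data.frame` of per-sample library sizes and TMM factors
#' @slot dispersion common NB dispersion estimate \eqn{\phi}
#' @slot params list of analysis parameters (design, filter, thresholds)
#'
#' @seealso [pairedLRT()], [groupLRT()], [deResults()]
#' @export
setClass("DEResultSet",
  representation(results = "data.frame", normFactors = "data.frame",
                 dispersion = "numeric", params = "list")
)

setValidity("DEResultSet", function(object) {
  need <- c("feature_id", "log2FC", "lrt_stat", "p_value", "fdr",
            "direction", "tested")
  msgs <- character()
  if (!all(need %in% colnames(object@results)))
    msgs <- c(msgs, paste("results must have columns:",
                          paste(need, collapse = ", ")))
  else {
    r <- object@results
    if (anyDuplicated(r$feature_id))
      msgs <- c(msgs, "duplicate feature_id in results")
    ok <- !is.na(r$p_value)
    if (any(r$lrt_stat[ok] < 0)) msgs <- c(msgs, "LRT statistic must be >= 0")
    if (any(r$fdr[ok] + 1e-12 < r$p_value[ok]))
      msgs <- c(msgs, "FDR must be >= p-value after BH")
  }
  if (length(object@dispersion) == 1L && object@dispersion < 0)
    msgs <- c(msgs, "dispersion must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Correlation ranking against a target lncRNA
#'
#' All candidate features ordered by Pearson correlation with a target
#' lncRNA over a set of samples; rank 1 is the most positively correlated
#' feature. Zero-variance features are excluded and accounted for.
#'
#' @slot target feature id of the target lncRNA
#' @slot ranking `data.frame` with columns `feature_id`, `r`, `rank`
#' @slot nSamples number of samples the correlations were computed over
#' @slot excluded `data.frame` with columns `feature_id`, `reason`
#' @slot transform expression transform used (`"logCPM"` or `"raw"`)
#'
#' @seealso [correlateTargetVsAll()], [rankSetEnrichment()]
#' @export
setClass("CorrelationRanking",
  representation(target = "character", ranking = "data.frame",
                 nSamples = "integer", excluded = "data.frame",
                 transform = "character")
)

setValidity("CorrelationRanking", function(object) {
  r <- object@ranking
  msgs <- character()
  if (!all(c("feature_id", "r", "rank") %in% colnames(r)))
    msgs <- c(msgs, "ranking must have columns feature_id, r, rank")
  else {
    if (nrow(r) && !identical(sort(r$rank), seq_len(nrow(r))))
      msgs <- c(msgs, "ranks must be a permutation of 1..m")
    if (any(abs(r$r) > 1 + 1e-12)) msgs <- c(msgs, "|r| must be <= 1")
    if (object@target %in% r$feature_id)
      msgs <- c(msgs, "target must be excluded from its own ranking")
  }
  if (length(msgs)) msgs else TRUE
})

#' Bipartite lncRNA-mRNA co-expression network
#'
#' Vertices are dual-cohort differentially expressed features split into
#' lncRNA and protein-coding classes; edges connect an lncRNA to a
#' protein-coding gene when their Pearson correlation falls in the extreme
#' positive or negative percentile of all candidate pairs.
#'
#' @slot vertices `data.frame` with columns `feature_id`, `class`, `degree`
#' @slot edges `data.frame` with columns `lnc_id`, `pcg_id`, `r`, `sign`
#' @slot params list: `edge_fraction`, `sample_subset`, thresholds, pool size
#'
#' @seealso [buildNetwork()], [hubReport()]
#' @export
setClass("CoexpressionNetwork",
  representation(vertices = "data.frame", edges = "data.frame",
                 params = "list")
)

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  v <- object@vertices
  msgs <- character()
  if (!all(c("lnc_id", "pcg_id", "r", "sign") %in% colnames(e)))
    msgs <- c(msgs, "edges must have columns lnc_id, pcg_id, r, sign")
  else if (nrow(e)) {
    if (any(abs(e$r) > 1 + 1e-12)) msgs <- c(msgs, "|r| must be <= 1")
    lnc <- v$feature_id[v$class == "lncRNA"]
    pcg <- v$feature_id[v$class == "protein_coding"]
    if (!all(e$lnc_id %in% lnc) || !all(e$pcg_id %in% pcg))
      msgs <- c(msgs, "every edge must join a listed lncRNA to a listed protein-coding vertex")
  }
  if (length(msgs)) msgs else TRUE
})
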