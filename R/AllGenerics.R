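#' @include AllClasses.R
NULL

#' Accessors for lncDiscoveR objects
#'
#' Accessor generics for the package's S4 containers: the sample sheet and
#' feature annotation of a [LncCountExperiment-class], the result table,
#' normalization factors and dispersion of a [DEResultSet-class], the
#' ranking table of a [CorrelationRanking-class], and the vertex/edge tables
#' of a [CoexpressionNetwork-class].
#'
#' @param x an object of the documented class
#' @return A `data.frame` (tables), `matrix` (`countsMatrix`) or `numeric`
#'   (`dispersionEstimate`).
#' @name accessors
#' @aliases sampleSheet featureAnnotation countsMatrix deResults normFactors
#'   dispersionEstimate rankingTable excludedFeatures networkVertices
#'   networkEdges networkParams
#' @examples
#' cfg <- simulationConfig(nFeatures = 50, nTrueDE = 5, seed = 1)
#' sim <- simulateDiscoveryCohort(cfg)
#' head(sampleSheet(sim$experiment))
#' head(featureAnnotation(sim$experiment))
NULL

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))
#' @rdname accessors
#' @export
setGeneric("featureAnnotation",
           function(x) standardGeneric("featureAnnotation"))
#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))
#' @rdname accessors
#' @export
setGeneric("deResults", function(x) standardGeneric("deResults"))
#' @rdname accessors
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))
#' @rdname accessors
#' @export
setGeneric("dispersionEstimate",
           function(x) standardGeneric("dispersionEstimate"))
#' @rdname accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))
#' @rdname accessors
#' @export
setGeneric("excludedFeatures", function(x) standardGeneric("excludedFeatures"))
#' @rdname accessors
#' @export
setGeneric("networkVertices", function(x) standardGeneric("networkVertices"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkParams", function(x) standardGeneric("networkParams"))

#' @rdname accessors
setMethod("sampleSheet", "LncCountExperiment", function(x) {
  df <- as.data.frame(colData(x))
  df$sample_id <- rownames(df)
  rownames(df) <- NULL
  df[, c("sample_id", "patient_id", "condition", "stage")]
})

#' @rdname accessors
setMethod("featureAnnotation", "LncCountExperiment", function(x) {
  df <- as.data.frame(rowData(x))
  df$feature_id <- rownames(x)
  rownames(df) <- NULL
  df[, c("feature_id", "symbol", "biotype", "is_lncRNA")]
})

#' @rdname accessors
setMethod("countsMatrix", "LncCountExperiment",
          function(x) assay(x, "counts"))

#' @rdname accessors
setMethod("deResults", "DEResultSet", function(x) x@results)
#' @rdname accessors
setMethod("normFactors", "DEResultSet", function(x) x@normFactors)
#' @rdname accessors
setMethod("dispersionEstimate", "DEResultSet", function(x) x@dispersion)

#' @rdname accessors
setMethod("rankingTable", "CorrelationRanking", function(x) x@ranking)
#' @rdname accessors
setMethod("excludedFeatures", "CorrelationRanking", function(x) x@excluded)

#' @rdname accessors
setMethod("networkVertices", "CoexpressionNetwork", function(x) x@vertices)
#' @rdname accessors
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkParams", "CoexpressionNetwork", function(x) x@params)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  discovery: %d matched pairs; confirmation: %d tumor / %d normal\n",
              object@nPairsDiscovery, object@nTumorConfirm,
              object@nNormalConfirm))
  cat(sprintf("  features: %d (%.0f%% lncRNA), %d with planted |log2FC| in [%g, %g]\n",
              object@nFeatures, 100 * object@fracLncRNA, object@nTrueDE,
              object@logfcRange[1], object@logfcRange[2]))
  cat(sprintf("  NB dispersion phi = %g; lnc/pcg baseline means %g / %g\n",
              object@dispersion, object@lncMeanCount, object@pcgMeanCount))
  cat(sprintf("  patient effect sd = %g; latent loading = %g; planted set = %d; seed = %d\n",
              object@patientEffectSd, object@latentFactorLoading,
              object@plantedSetSize, object@seed))
})

setMethod("show", "DEResultSet", function(object) {
  r <- object@results
  cat(sprintf("DEResultSet: %d features (%d tested), design = %s\n",
              nrow(r), sum(r$tested), object@params$design))
  cat(sprintf("  common dispersion phi = %.4g\n", object@dispersion))
  thr <- object@params$fdr
  if (!is.null(thr))
    cat(sprintf("  %d features at FDR < %g\n",
                sum(r$fdr < thr, na.rm = TRUE), thr))
  cat("  head of results:\n")
  print(head(r, 3L))
})

setMethod("show", "CorrelationRanking", function(object) {
  cat(sprintf("CorrelationRanking: target %s vs %d features over %d samples (%s)\n",
              object@target, nrow(object@ranking), object@nSamples,
              object@transform))
  if (nrow(object@excluded))
    cat(sprintf("  %d features excluded (zero variance)\n",
                nrow(object@excluded)))
  cat("  strongest positive:\n")
  print(head(object@ranking[order(object@ranking$rank), ], 3L))
})

setMethod("show", "CoexpressionNetwork", function(object) {
  v <- object@vertices
  cat(sprintf("CoexpressionNetwork: %d lncRNA + %d protein-coding vertices, %d edges\n",
              sum(v$class == "lncRNA"), sum(v$class == "protein_coding"),
              nrow(object@edges)))
  cat(sprintf("  edge fraction %g over %d candidate pairs (%s samples)\n",
              object@params$edge_fraction, object@params$n_pairs_defined,
              object@params$sample_subset))
})
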