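#' @include nbglm.R
NULL

.asResultFrame <- function(x, fdrCol = "fdr") {
  if (is(x, "DEResultSet")) x <- deResults(x)
  if (!is.data.frame(x)) stop("expected a DEResultSet or data.frame")
  x
}

#' Confirm discovery hits in a second cohort
#'
#' Intersects two differential-expression result tables: a feature is a
#' confirmed hit when its discovery FDR is strictly below `fdrDisc`
#' (default 0.2, suited to a 3-pair cohort), its confirmation FDR is
#' strictly below `fdrConf` (default 0.05, suited to a large cohort), and
#' — by default — the effect direction agrees across cohorts. Features
#' absent from the confirmation cohort are never confirmed.
#'
#' @param discovery,confirmation [DEResultSet-class] objects or data frames
#'   with columns `feature_id`, `log2FC` (or `logFC`), and `fdr`; the
#'   confirmation table may instead carry its FDR in `fdr_confirm`
#' @param fdrDisc,fdrConf strict FDR thresholds for the two cohorts
#' @param requireDirectionMatch drop hits whose direction flips between
#'   cohorts?
#' @param annotation optional annotation `data.frame` used to attach
#'   `symbol` and `biotype`
#' @return A `data.frame` of confirmed hits with columns `feature_id`,
#'   `symbol`, `direction`, `log2FC`, `fdr_discovery`, `fdr_confirmation`,
#'   `biotype`.
#' @examples
#' t2 <- readDETable(system.file("extdata", "table2.tsv",
#'                               package = "lncDiscoveR"))
#' disc <- data.frame(feature_id = t2$transcript_id, log2FC = t2$logFC,
#'                    fdr = t2$fdr, symbol = t2$symbol, biotype = t2$biotype)
#' conf <- data.frame(feature_id = t2$transcript_id, log2FC = t2$logFC,
#'                    fdr = t2$fdr_confirm)
#' nrow(confirmHits(disc, conf))
#' @export
confirmHits <- function(discovery, confirmation, fdrDisc = 0.2,
                        fdrConf = 0.05, requireDirectionMatch = TRUE,
                        annotation = NULL) {
  d <- .asResultFrame(discovery)
  cf <- .asResultFrame(confirmation)
  if (!"log2FC" %in% colnames(d) && "logFC" %in% colnames(d))
    d$log2FC <- d$logFC
  if (!"log2FC" %in% colnames(cf) && "logFC" %in% colnames(cf))
    cf$log2FC <- cf$logFC
  if (!"fdr" %in% colnames(cf) && "fdr_confirm" %in% colnames(cf))
    cf$fdr <- cf$fdr_confirm
  .requireColumns(d, c("feature_id", "log2FC", "fdr"), "discovery results")
  .requireColumns(cf, c("feature_id", "fdr"), "confirmation results")
  if (anyDuplicated(d$feature_id))
    stop("duplicate feature id(s) in discovery results")
  if (anyDuplicated(cf$feature_id))
    stop("duplicate feature id(s) in confirmation results")

  idx <- match(d$feature_id, cf$feature_id)
  pass <- !is.na(d$fdr) & d$fdr < fdrDisc &
    !is.na(idx) & !is.na(cf$fdr[idx]) & cf$fdr[idx] < fdrConf
  if (requireDirectionMatch && "log2FC" %in% colnames(cf)) {
    same <- sign(d$log2FC) == sign(cf$log2FC[idx])
    pass <- pass & !is.na(same) & same
  }

  hits <- data.frame(
    feature_id = d$feature_id[pass],
    symbol = if ("symbol" %in% colnames(d)) d$symbol[pass]
             else d$feature_id[pass],
    direction = ifelse(d$log2FC[pass] > 0, "up", "down"),
    log2FC = d$log2FC[pass],
    fdr_discovery = d$fdr[pass],
    fdr_confirmation = cf$fdr[idx][pass],
    biotype = if ("biotype" %in% colnames(d)) d$biotype[pass]
              else rep(NA_character_, sum(pass)),
    row.names = NULL)
  if (!is.null(annotation)) {
    j <- match(hits$feature_id, annotation$feature_id)
    hits$symbol <- ifelse(is.na(j), hits$symbol, annotation$symbol[j])
    hits$biotype <- ifelse(is.na(j), hits$biotype, annotation$biotype[j])
  }
  hits
}

#' Partition confirmed hits by direction
#'
#' Splits a confirmed-hit table into up- and down-regulated subsets by the
#' sign of the discovery log2 fold change. A fold change of exactly zero
#' cannot belong to a hit and raises an error.
#'
#' @param hits a confirmed-hit `data.frame` from [confirmHits()]
#' @return A list with elements `up` and `down`.
#' @examples
#' h <- data.frame(feature_id = c("a", "b"), log2FC = c(2, -3))
#' lengths(partitionByDirection(h))
#' @export
partitionByDirection <- function(hits) {
  .requireColumns(hits, c("feature_id", "log2FC"), "hits")
  if (any(hits$log2FC == 0))
    stop("log2FC of exactly 0 cannot be a confirmed hit: ",
         paste(hits$feature_id[hits$log2FC == 0], collapse = ", "))
  list(up = hits[hits$log2FC > 0, , drop = FALSE],
       down = hits[hits$log2FC < 0, , drop = FALSE])
}

#' Flag novel hits against a literature-known list
#'
#' Marks each hit as novel when its gene symbol is absent from the given
#' known-id set (case-sensitive exact match on symbol).
#'
#' @param hits a confirmed-hit `data.frame` with a `symbol` column
#' @param knownIds character vector of known symbols (see [readIdList()])
#' @return `hits` with a logical `novel` column appended.
#' @examples
#' h <- data.frame(feature_id = "x", symbol = "CCAT1")
#' annotateNovelty(h, c("CCAT1", "MEG3"))$novel
#' @export
annotateNovelty <- function(hits, knownIds) {
  .requireColumns(hits, "symbol", "hits")
  hits$novel <- !(hits$symbol %in% knownIds)
  hits
}
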