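#' @include AllGenerics.R normalize.R
NULL

#' Pearson product-moment correlation
#'
#' The standard product-moment correlation
#' \eqn{r = \sum (x_i - \bar x)(y_i - \bar y) / \sqrt{\sum (x_i - \bar
#' x)^2 \sum (y_i - \bar y)^2}}. Constant input is an error: the caller is
#' expected to exclude zero-variance features.
#'
#' @param x,y equal-length numeric vectors of length >= 3
#' @return Correlation in \[-1, 1\].
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop("constant vector: correlation undefined")
  max(-1, min(1, sum(dx * dy) / sqrt(sx * sy)))
}

## log2(CPM + 0.5) on TMM effective library sizes.
.logCPM <- function(counts, norm = NULL) {
  if (is.null(norm)) norm <- tmmNormalize(counts)
  eff <- norm$eff_lib_size[match(colnames(counts), norm$sample_id)]
  log2(sweep(counts, 2L, eff / 1e6, `/`) + 0.5)
}

#' Rank all genes by correlation with a target lncRNA
#'
#' Transforms expression to `log2(CPM + 0.5)` (TMM effective library
#' sizes) unless `transform = "raw"`, then computes the Pearson correlation
#' between the target lncRNA and every candidate feature over the chosen
#' samples. Features with zero variance are excluded and recorded; the
#' remainder are densely ranked, rank 1 = most positive correlation, ties
#' broken by feature id so the ranking is deterministic. The target never
#' appears in its own ranking.
#'
#' @param x [LncCountExperiment-class] or count matrix
#' @param target feature id of the target lncRNA
#' @param candidates feature ids to rank (default: all other features)
#' @param samples sample ids to use (default: tumor samples, matching the
#'   cohort the network correlations are defined on)
#' @param transform `"logCPM"` (default) or `"raw"`
#' @param sheet sample sheet, needed for the tumor default when `x` is a
#'   matrix
#' @return A [CorrelationRanking-class].
#' @examples
#' cfg <- simulationConfig(nFeatures = 100, nTumorConfirm = 40,
#'                         nNormalConfirm = 10, seed = 5)
#' sim <- simulateDiscoveryCohort(cfg)
#' conf <- simulateConfirmationCohort(cfg, sim$truth)
#' correlateTargetVsAll(conf, sim$truth$feature_id[sim$truth$is_target])
#' @export
correlateTargetVsAll <- function(x, target, candidates = NULL,
                                 samples = NULL,
                                 transform = c("logCPM", "raw"),
                                 sheet = NULL) {
  transform <- match.arg(transform)
  if (is(x, "LncCountExperiment")) {
    if (is.null(sheet)) sheet <- sampleSheet(x)
    x <- countsMatrix(x)
  }
  if (!target %in% rownames(x)) stop("target not in matrix: ", target)
  if (is.null(samples)) {
    samples <- if (!is.null(sheet))
      sheet$sample_id[sheet$condition == "tumor"] else colnames(x)
  }
  samples <- intersect(colnames(x), samples)
  if (length(samples) < 3L) stop("need at least 3 samples")
  if (is.null(candidates)) candidates <- rownames(x)
  candidates <- setdiff(candidates, target)   # self-exclusion

  expr <- if (transform == "logCPM") .logCPM(x) else x
  tv <- expr[target, samples]
  if (sd(tv) == 0) stop("target has zero variance over the selected samples")

  rvals <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    yv <- expr[candidates[i], samples]
    if (sd(yv) > 0) rvals[i] <- pearsonR(tv, yv)
  }
  excl <- is.na(rvals)
  kept <- data.frame(feature_id = candidates[!excl], r = rvals[!excl])
  ord <- order(-kept$r, kept$feature_id, method = "radix")
  kept <- kept[ord, , drop = FALSE]
  kept$rank <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  new("CorrelationRanking", target = target, ranking = kept,
      nSamples = length(samples),
      excluded = data.frame(feature_id = candidates[excl],
                            reason = rep("zero variance", sum(excl))),
      transform = transform)
}

## Exact null of the rank-sum of nSet ranks drawn without replacement from
## 1..m: subset-sum counting by dynamic programming.
.rankSumExactPLe <- function(sObs, m, nSet) {
  ## counts[s+1, k+1] built iteratively over items 1..m
  maxS <- sum((m - nSet + 1):m)
  counts <- matrix(0, maxS + 1L, nSet + 1L)
  counts[1L, 1L] <- 1
  for (item in seq_len(m)) {
    for (k in rev(seq_len(nSet))) {
      nz <- which(counts[, k] > 0)
      if (length(nz))
        counts[nz + item, k + 1L] <- counts[nz + item, k + 1L] +
          counts[nz, k]
    }
  }
  tot <- choose(m, nSet)
  sum(counts[seq_len(min(sObs, maxS) + 1L), nSet + 1L]) / tot
}

#' Rank-shift enrichment of a gene set in a correlation ranking
#'
#' Tests whether the correlation ranks of a gene set are shifted towards
#' the positively correlated end relative to background (all other ranked
#' features), using the Mann-Whitney rank-sum statistic on the ranks. The
#' one-sided p-value is for "set more positively correlated than
#' background" (smaller ranks); a two-sided p is also reported. For small
#' rankings (`m <= exactLimit`) the exact permutation null of the rank sum
#' is used; otherwise the normal approximation with continuity correction
#' (ties cannot occur after dense ranking).
#'
#' @param ranking a [CorrelationRanking-class]
#' @param set character vector of member feature ids
#' @param setId label for the result row
#' @param exactLimit largest ranking size for the exact null
#' @return A one-row `data.frame`: `set_id`, `set_size`, `m`, `U`,
#'   `mean_rank_set`, `mean_rank_background`, `direction`, `p_one_sided`,
#'   `p_two_sided`, `method`.
#' @examples
#' rk <- new("CorrelationRanking", target = "t",
#'           ranking = data.frame(feature_id = letters[1:10],
#'                                r = seq(0.9, -0.9, length.out = 10),
#'                                rank = 1:10),
#'           nSamples = 10L,
#'           excluded = data.frame(feature_id = character(),
#'                                 reason = character()),
#'           transform = "raw")
#' rankSetEnrichment(rk, c("a", "b", "c"))
#' @export
rankSetEnrichment <- function(ranking, set, setId = "set",
                              exactLimit = 30L) {
  stopifnot(is(ranking, "CorrelationRanking"))
  rk <- rankingTable(ranking)
  inSet <- rk$feature_id %in% set
  nS <- sum(inSet)
  if (nS == 0L) stop("no member of set '", setId, "' is in the ranking")
  nB <- sum(!inSet)
  if (nB == 0L) stop("set '", setId, "' covers the whole ranking; no background")
  m <- nS + nB
  sObs <- sum(rk$rank[inSet])
  U <- sObs - nS * (nS + 1) / 2      # Mann-Whitney U of the set ranks

  if (m <= exactLimit) {
    pLe <- .rankSumExactPLe(sObs, m, nS)
    pGe <- 1 - .rankSumExactPLe(sObs - 1L, m, nS)
    method <- "exact"
  } else {
    E <- nS * (m + 1) / 2
    V <- nS * nB * (m + 1) / 12
    pLe <- pnorm((sObs - E + 0.5) / sqrt(V))
    pGe <- pnorm((sObs - E - 0.5) / sqrt(V), lower.tail = FALSE)
    method <- "normal approximation"
  }
  meanSet <- mean(rk$rank[inSet])
  meanBg <- mean(rk$rank[!inSet])
  data.frame(set_id = setId, set_size = nS, m = m, U = U,
             mean_rank_set = meanSet, mean_rank_background = meanBg,
             direction = ifelse(meanSet < meanBg, "positive", "negative"),
             p_one_sided = min(1, pLe), p_two_sided = min(1, 2 * min(pLe, pGe)),
             method = method, row.names = NULL)
}
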