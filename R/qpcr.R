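#' @include AllClasses.R
NULL

#' qPCR relative expression by the 2^-deltaCt method
#'
#' Relative expression is `2^-(ctTarget - ctReference)`: one cycle fewer on
#' the target (at a fixed reference) doubles the estimate. Missing Ct
#' values (undetermined wells) propagate as `NA`, never as zero.
#'
#' @param ctTarget,ctReference numeric Ct values (cycles)
#' @return Positive numeric relative expression (NA where a Ct is missing).
#' @examples
#' relativeExpression(25, 20)   # 2^-5
#' @export
relativeExpression <- function(ctTarget, ctReference) {
  2^(-(ctTarget - ctReference))
}

#' Build per-sample qPCR records from duplicate-well Ct tables
#'
#' Averages duplicate wells on the Ct scale (target and reference
#' separately), forms `delta_ct = ct_target - ct_reference` and the
#' `2^-delta_ct` relative expression. Rows with an undetermined mean Ct
#' keep `NA` relative expression; paired analyses drop such pairs and log
#' the count.
#'
#' @param table `data.frame` with columns `patient_id`, `tissue`, `stage`,
#'   `target`, `ct_rep1`, `ct_rep2`, `ref_ct_rep1`, `ref_ct_rep2`
#' @return A `data.frame` of records with `ct_target`, `ct_reference`,
#'   `delta_ct` and `rel_expr` columns.
#' @examples
#' tab <- simulateQpcrCohort(6, effectDeltaCt = 1, noiseSd = 0.3, seed = 1)
#' head(qpcrRecords(tab))
#' @export
qpcrRecords <- function(table) {
  .requireColumns(table, c("patient_id", "tissue", "stage", "target",
                           "ct_rep1", "ct_rep2", "ref_ct_rep1",
                           "ref_ct_rep2"), "qPCR table")
  ctT <- rowMeans(table[, c("ct_rep1", "ct_rep2")], na.rm = FALSE)
  ctR <- rowMeans(table[, c("ref_ct_rep1", "ref_ct_rep2")], na.rm = FALSE)
  data.frame(patient_id = table$patient_id, tissue = table$tissue,
             stage = table$stage, target = table$target,
             ct_target = ctT, ct_reference = ctR,
             delta_ct = ctT - ctR,
             rel_expr = relativeExpression(ctT, ctR))
}

## Exact null distribution of the signed-rank statistic: counts over the
## 2^n equiprobable sign assignments, computed by dynamic programming over
## doubled midranks (integers even under ties).
.signedRankExactP <- function(w2, ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)   # index i = probability weight of W2 = i-1
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(ranks2)
  w2 <- round(w2)
  pLe <- sum(counts[seq_len(w2 + 1L)])
  pGe <- sum(counts[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(pLe, pGe))
}

#' Wilcoxon signed-rank test for matched pairs
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (Wilcoxon convention) and tied absolute differences receive
#' midranks. For `n <= exactLimit` non-zero pairs the p-value comes from
#' the exact null distribution over all `2^n` sign assignments (computed by
#' dynamic programming, which enumerates the same distribution); above it,
#' a normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x paired differences, or the first member of each pair when `y`
#'   is given
#' @param y optional second member of each pair (`x - y` is tested)
#' @param exactLimit largest n for which the exact distribution is used
#' @return A list: `test`, `statistic` (W, sum of positive-difference
#'   ranks), `p_value`, `method` ("exact" or "normal approximation"),
#'   `n_used`, `n_zero_dropped`.
#' @examples
#' wilcoxonSignedRank(c(1.2, 0.8, 2.1, 0.4, 1.7, 0.9))
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactLimit = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nZero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(test = "wilcoxon_signed_rank", statistic = 0,
                p_value = 1, method = "degenerate", n_used = 0L,
                n_zero_dropped = nZero))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactLimit) {
    p <- .signedRankExactP(2 * W, as.integer(round(2 * r)))
    method <- "exact"
  } else {
    E <- n * (n + 1) / 4
    tie <- table(r)
    V <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (W - E - sign(W - E) * 0.5) / sqrt(V)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(test = "wilcoxon_signed_rank", statistic = W, p_value = p,
       method = method, n_used = n, n_zero_dropped = nZero)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with the \eqn{\chi^2_{k-1}} reference
#' distribution, for comparing expression levels across tumor stages.
#'
#' @param values numeric observations
#' @param groups group labels, same length as `values`
#' @return A list: `test`, `statistic` (H), `df`, `p_value`, `groups`.
#' @examples
#' kruskalWallis(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
kruskalWallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups)[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("Kruskal-Wallis requires at least 2 groups")
  if (any(tabulate(groups) == 0L)) stop("every group must be nonempty")
  N <- length(values)
  if (N < 3L) stop("Kruskal-Wallis requires at least 3 observations")
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie <- table(values)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  list(test = "kruskal_wallis", statistic = H, df = k - 1, p_value = p,
       groups = levels(groups))
}

## Standardized pairwise rank-sum statistic (tie-corrected) for two groups.
.pairZ <- function(a, b) {
  nA <- length(a); nB <- length(b); N <- nA + nB
  r <- rank(c(a, b))
  W <- sum(r[seq_len(nA)])
  E <- nA * (N + 1) / 2
  V <- nA * nB / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(c(z = 0, var = 0))
  c(z = (W - E) / sqrt(V), var = V)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, the Wilcoxon rank-sum statistic is computed on
#' the two groups alone, standardized with tie correction, and referred to
#' the studentized-range distribution with `k` groups and infinite degrees
#' of freedom (`q = |z| * sqrt(2)`), giving family-wise p-values. With
#' `k = 2` this reduces exactly to the two-sided normal-approximation
#' rank-sum test. An optional permutation mode calibrates the family-wise
#' p against the permutation distribution of the maximum standardized
#' statistic.
#'
#' @param values numeric observations
#' @param groups group labels, same length as `values`; every group must
#'   have at least 2 observations
#' @param method `"studentized-range"` (default) or `"permutation"`
#' @param nPerm permutations for the permutation mode
#' @param seed seed for the permutation mode
#' @return A `data.frame` with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `z`, `q`, `p_value`.
#' @examples
#' steelDwass(c(rnorm(8), rnorm(8), rnorm(8) + 2),
#'            rep(c("a", "b", "c"), each = 8))
#' @export
steelDwass <- function(values, groups,
                       method = c("studentized-range", "permutation"),
                       nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups)[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("Steel-Dwass requires at least 2 groups")
  if (any(tabulate(groups) < 2L))
    stop("every group must have at least 2 observations")
  lev <- levels(groups)
  pairs <- utils::combn(k, 2L)
  byGroup <- split(values, groups)

  zq <- apply(pairs, 2L, function(ij) {
    st <- .pairZ(byGroup[[ij[1]]], byGroup[[ij[2]]])
    if (st["var"] == 0) c(0, 0) else c(st["z"], abs(st["z"]) * sqrt(2))
  })
  z <- zq[1L, ]; q <- zq[2L, ]
  degenerate <- vapply(seq_len(ncol(pairs)), function(j) {
    g <- c(byGroup[[pairs[1, j]]], byGroup[[pairs[2, j]]])
    length(unique(g)) == 1L
  }, logical(1))

  if (method == "studentized-range") {
    p <- ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  } else {
    set.seed(as.integer(seed))
    nG <- tabulate(groups)
    qPerm <- matrix(0, nPerm, ncol(pairs))
    for (b in seq_len(nPerm)) {
      perm <- split(sample(values), rep(seq_len(k), nG))
      qPerm[b, ] <- apply(pairs, 2L, function(ij) {
        st <- .pairZ(perm[[ij[1]]], perm[[ij[2]]])
        if (st["var"] == 0) 0 else abs(st["z"]) * sqrt(2)
      })
    }
    maxQ <- apply(qPerm, 1L, max)
    p <- vapply(q, function(qi) mean(maxQ >= qi - 1e-12), numeric(1))
  }
  p[degenerate] <- 1
  data.frame(group1 = lev[pairs[1, ]], group2 = lev[pairs[2, ]],
             n1 = tabulate(groups)[pairs[1, ]],
             n2 = tabulate(groups)[pairs[2, ]],
             z = z, q = q, p_value = pmin(1, p), row.names = NULL)
}

#' Paired tumor-vs-normal test on qPCR records
#'
#' Runs the Wilcoxon signed-rank test on matched tumor/normal relative
#' expression for each target in a record table. Pairs with a missing
#' relative expression on either side are dropped and counted.
#'
#' @param records a record `data.frame` from [qpcrRecords()]
#' @return A `data.frame` with one row per target: `target`, `n_pairs`,
#'   `n_dropped`, `statistic`, `p_value`, `median_ratio` (tumor / normal
#'   median of within-pair `2^-deltaCt` ratios).
#' @examples
#' tab <- simulateQpcrCohort(20, effectDeltaCt = 1, noiseSd = 0.5, seed = 2)
#' qpcrPairedTest(qpcrRecords(tab))
#' @export
qpcrPairedTest <- function(records) {
  do.call(rbind, lapply(split(records, records$target), function(rec) {
    tum <- rec[rec$tissue == "tumor", ]
    nor <- rec[rec$tissue == "normal", ]
    j <- match(tum$patient_id, nor$patient_id)
    t_expr <- tum$rel_expr
    n_expr <- nor$rel_expr[j]
    ok <- !is.na(t_expr) & !is.na(n_expr)
    if (sum(!ok))
      message(sum(!ok), " pair(s) dropped (undetermined Ct) for target ",
              rec$target[1])
    wt <- wilcoxonSignedRank(t_expr[ok], n_expr[ok])
    data.frame(target = rec$target[1], n_pairs = sum(ok),
               n_dropped = sum(!ok), statistic = wt$statistic,
               p_value = wt$p_value,
               median_ratio = median(t_expr[ok] / n_expr[ok]),
               row.names = NULL)
  }))
}

#' Stage-wise analysis of tumor qPCR levels
#'
#' For each target, compares tumor relative expression across stages (CA
#' and I-IV) with the Kruskal-Wallis test; when that is significant at
#' `alpha`, an all-pairs Steel-Dwass table is appended. Stages with fewer
#' than 2 tumors are excluded from the pairwise stage with a warning.
#'
#' @param records a record `data.frame` from [qpcrRecords()]
#' @param alpha significance level gating the pairwise stage
#' @return A named list (one element per target), each a list with
#'   `target`, `kruskal` (list from [kruskalWallis()]) and `pairwise`
#'   (`data.frame` from [steelDwass()], or `NULL`).
#' @examples
#' tab <- simulateQpcrCohort(60, effectDeltaCt = 1, noiseSd = 0.5, seed = 3)
#' stagewiseAnalysis(qpcrRecords(tab))
#' @export
stagewiseAnalysis <- function(records, alpha = 0.05) {
  lapply(split(records, records$target), function(rec) {
    tum <- rec[rec$tissue == "tumor" & !is.na(rec$stage) &
                 !is.na(rec$rel_expr), ]
    kw <- kruskalWallis(tum$rel_expr, tum$stage)
    pairwise <- NULL
    if (kw$p_value < alpha) {
      sizes <- table(tum$stage)
      small <- names(sizes)[sizes < 2L]
      if (length(small)) {
        warning("stage(s) with < 2 tumors excluded from Steel-Dwass: ",
                paste(small, collapse = ", "))
        tum <- tum[!tum$stage %in% small, ]
      }
      pairwise <- steelDwass(tum$rel_expr, tum$stage)
    }
    list(target = rec$target[1], kruskal = kw, pairwise = pairwise)
  })
}
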