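#' @include AllClasses.R
NULL

#' Trimmed-mean-of-M-values (TMM) normalization
#'
#' Computes per-sample scaling factors by the TMM method: for each sample
#' versus a reference, per-feature log2 expression ratios (M) and average
#' log2 abundances (A) are formed over features nonzero in both samples,
#' the most extreme 30% of M values per tail and 5% of A values per tail
#' are trimmed, and the factor is the precision-weighted mean of the
#' surviving M values (binomial asymptotic-variance weights). The reference
#' is the sample whose upper-quartile expression is closest to the mean
#' upper quartile; factors are rescaled to geometric mean 1, so the
#' effective library size is `lib_size * norm_factor`.
#'
#' @param counts integer feature-by-sample matrix or a
#'   [LncCountExperiment-class]
#' @param logratioTrim fraction of M values trimmed from each tail
#' @param sumTrim fraction of A values trimmed from each tail
#' @return A `data.frame` with columns `sample_id`, `lib_size`,
#'   `norm_factor`, `eff_lib_size`.
#' @examples
#' m <- matrix(rpois(600, 50), 100, 6,
#'             dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
#' tmmNormalize(m)
#' @export
tmmNormalize <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  if (is(counts, "LncCountExperiment")) counts <- countsMatrix(counts)
  if (ncol(counts) < 2L) stop("normalization needs at least 2 samples")
  libSize <- colSums(counts)
  if (any(libSize == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[libSize == 0], collapse = ", "))

  ## reference: upper quartile of depth-scaled counts closest to the mean
  uq <- apply(counts, 2L, function(x) quantile(x, 0.75)) / libSize
  ref <- which.min(abs(uq - mean(uq)))

  factors <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    .tmmPair(counts[, k], counts[, ref], libSize[k], libSize[ref],
             logratioTrim, sumTrim)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  data.frame(sample_id = colnames(counts), lib_size = libSize,
             norm_factor = factors,
             eff_lib_size = libSize * factors, row.names = NULL)
}

.tmmPair <- function(obs, ref, nO, nR, logratioTrim, sumTrim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2) || sum(w[keep2]) == 0) return(1)
  f <- 2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}
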