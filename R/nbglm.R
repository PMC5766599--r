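#' @include AllGenerics.R normalize.R
NULL

## Design matrices for the two nested models. Paired: the full model has a
## patient regressor per pair plus the tumor indicator; the reduced model
## drops only the tumor indicator.
.designMatrices <- function(sheet, paired = TRUE) {
  cond <- factor(sheet$condition, levels = .CONDITIONS)
  if (paired) {
    validatePairing(sheet)
    patient <- factor(sheet$patient_id)
    full <- stats::model.matrix(~ patient + cond)
    reduced <- stats::model.matrix(~ patient)
  } else {
    full <- stats::model.matrix(~ cond)
    reduced <- stats::model.matrix(~ 1, data = data.frame(x = cond))
  }
  colnames(full)[ncol(full)] <- "condtumor"
  if (qr(full)$rank < ncol(full)) stop("design matrix is not full rank")
  list(full = full, reduced = reduced)
}

## Thin wrapper around the C++ IRLS kernel for a count matrix.
.fitMatrix <- function(Y, X, offset, phi, crAdjust = FALSE) {
  .nbGlmFitCpp(as.matrix(Y), X, as.numeric(offset), as.numeric(phi),
               crAdjust, 1e-8, 100L)
}

#' Fit a negative-binomial GLM for one feature
#'
#' Fits a log-link NB GLM by iteratively reweighted least squares at a
#' fixed dispersion `phi` (variance \eqn{\mu + \phi\mu^2}; `phi = 0` is the
#' Poisson limit). Convergence is declared when the largest coefficient
#' update falls below `1e-8`, within 100 iterations. The returned
#' log-likelihood is the exact NB log-likelihood at the fitted means.
#'
#' @param y nonnegative integer counts for one feature
#' @param design numeric design matrix (rows = samples), full rank
#' @param offset log effective library sizes
#' @param phi NB dispersion
#' @return A list with `beta` (named coefficients), `mu` (fitted means),
#'   `loglik`, `converged`, `iter`.
#' @examples
#' y <- c(5, 9, 3, 40, 40, 21)
#' X <- cbind(1, rep(c(0, 1), each = 3))
#' fitNbGlm(y, X, offset = rep(0, 6), phi = 0.1)
#' @export
fitNbGlm <- function(y, design, offset = rep(0, length(y)), phi = 0) {
  stopifnot(length(y) == nrow(design), length(offset) == length(y),
            phi >= 0)
  fit <- .fitMatrix(matrix(y, nrow = 1L), design, offset, phi)
  beta <- drop(fit$beta)
  names(beta) <- colnames(design)
  mu <- if (all(is.finite(beta))) exp(offset + drop(design %*% beta))
        else rep(NA_real_, length(y))
  list(beta = beta, mu = mu, loglik = fit$loglik[1],
       converged = fit$converged[1], iter = fit$iter[1])
}

#' Estimate the common NB dispersion by Cox-Reid profile likelihood
#'
#' Maximizes the Cox-Reid adjusted profile log-likelihood of the full
#' (patient + condition, or condition-only) model, summed over features,
#' by a bounded one-dimensional search on log(phi) in `[1e-6, 10]`.
#' Features with identical counts in every sample carry no dispersion
#' information and are excluded (with a message).
#'
#' @param counts integer feature-by-sample matrix or
#'   [LncCountExperiment-class]
#' @param sheet sample sheet (`data.frame`); taken from the experiment when
#'   omitted
#' @param norm normalization table from [tmmNormalize()]; computed when
#'   omitted
#' @param paired paired (patient + condition) or unpaired design
#' @return The common dispersion estimate (numeric scalar).
#' @examples
#' cfg <- simulationConfig(nFeatures = 300, nTrueDE = 0, seed = 3)
#' sim <- simulateDiscoveryCohort(cfg)
#' estimateCommonDispersion(sim$experiment)
#' @export
estimateCommonDispersion <- function(counts, sheet = NULL, norm = NULL,
                                     paired = TRUE) {
  if (is(counts, "LncCountExperiment")) {
    if (is.null(sheet)) sheet <- sampleSheet(counts)
    counts <- countsMatrix(counts)
  }
  if (is.null(sheet)) stop("a sample sheet is required")
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  if (is.null(norm)) norm <- tmmNormalize(counts)
  offset <- log(norm$eff_lib_size[match(colnames(counts), norm$sample_id)])
  X <- .designMatrices(sheet, paired)$full

  constant <- apply(counts, 1L, function(x) all(x == x[1]))
  if (any(constant))
    message(sum(constant),
            " feature(s) with identical counts in every sample excluded",
            " from dispersion estimation")
  Y <- counts[!constant, , drop = FALSE]
  if (!nrow(Y)) stop("no informative features for dispersion estimation")

  apl <- function(logPhi) {
    fit <- .fitMatrix(Y, X, offset, exp(logPhi), crAdjust = TRUE)
    ok <- is.finite(fit$loglik) & is.finite(fit$cr)
    if (!any(ok))
      stop("dispersion search produced non-finite likelihoods for all features")
    sum(fit$loglik[ok] - fit$cr[ok])
  }
  opt <- optimize(apl, interval = log(c(1e-6, 10)), maximum = TRUE,
                  tol = 1e-3)
  exp(opt$maximum)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment: with order statistics \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, the adjusted value for \eqn{p_{(i)}} is
#' \eqn{\min_{j \ge i} m\, p_{(j)} / j}, capped at 1. Missing p-values are
#' propagated and do not count toward `m`.
#'
#' @param p numeric p-values in \[0, 1\] (NA allowed)
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  o <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[ok][o]))
  out[ok][o] <- adj
  out
}

## Shared LRT engine for the paired and unpaired tests.
.nbLRT <- function(counts, sheet, norm, phi, minExpressedSamples, paired,
                   fdr) {
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stop("sample sheet does not cover all samples")
  if (is.null(norm)) norm <- tmmNormalize(counts)
  offset <- log(norm$eff_lib_size[match(colnames(counts), norm$sample_id)])
  des <- .designMatrices(sheet, paired)
  if (is.null(phi))
    phi <- estimateCommonDispersion(counts, sheet, norm, paired)

  tested <- rowSums(counts > 0) >= minExpressedSamples
  res <- data.frame(feature_id = rownames(counts), log2FC = NA_real_,
                    lrt_stat = NA_real_, p_value = NA_real_, fdr = NA_real_,
                    direction = NA_character_, tested = tested)
  if (any(tested)) {
    Y <- counts[tested, , drop = FALSE]
    full <- .fitMatrix(Y, des$full, offset, phi)
    red <- .fitMatrix(Y, des$reduced, offset, phi)
    stat <- 2 * (full$loglik - red$loglik)
    bad <- which(stat < -1e-4)
    if (length(bad))
      stop("reduced model exceeded full-model likelihood beyond tolerance for feature(s): ",
           paste(rownames(Y)[head(bad, 5)], collapse = ", "),
           " (optimizer failure)")
    stat <- pmax(stat, 0)
    df <- ncol(des$full) - ncol(des$reduced)
    p <- pchisq(stat, df = df, lower.tail = FALSE)
    conv <- full$converged & red$converged
    p[!conv] <- NA_real_   # non-convergence: flagged, never fabricated
    lfc <- full$beta[, ncol(des$full)] / log(2)
    res$log2FC[tested] <- lfc
    res$lrt_stat[tested] <- stat
    res$p_value[tested] <- p
    res$direction[tested] <- ifelse(lfc > 0, "up",
                                    ifelse(lfc < 0, "down", NA))
  }
  res$fdr <- bhAdjust(res$p_value)
  new("DEResultSet", results = res, normFactors = norm,
      dispersion = phi,
      params = list(design = if (paired) "paired" else "group",
                    min_expressed_samples = minExpressedSamples,
                    fdr = fdr, n_samples = ncol(counts)))
}

#' Paired negative-binomial likelihood-ratio test
#'
#' The discovery-cohort differential-expression test: for every feature,
#' two nested NB GLMs are fitted at a common Cox-Reid dispersion — a
#' reduced model with only the patient regressor and a full model with
#' patient plus tumor/normal condition — and compared by a likelihood-ratio
#' test, `2(l_full - l_reduced)` against \eqn{\chi^2_1}. log2 fold changes
#' (tumor vs normal) come from the condition coefficient; FDR is
#' Benjamini-Hochberg over tested features. Features with nonzero counts in
#' fewer than `minExpressedSamples` samples are reported untested; fits
#' that do not converge are reported with a missing p-value.
#'
#' @param x [LncCountExperiment-class] or integer count matrix
#' @param sheet sample sheet (required when `x` is a matrix)
#' @param norm normalization table from [tmmNormalize()] (computed when
#'   omitted)
#' @param phi common NB dispersion (estimated when omitted)
#' @param minExpressedSamples low-count filter: minimum samples with a
#'   nonzero count
#' @param fdr significance threshold recorded in the result metadata
#' @return A [DEResultSet-class].
#' @examples
#' sim <- simulateDiscoveryCohort(simulationConfig(nFeatures = 200,
#'                                                 nTrueDE = 10, seed = 2))
#' pairedLRT(sim$experiment)
#' @export
pairedLRT <- function(x, sheet = NULL, norm = NULL, phi = NULL,
                      minExpressedSamples = 2L, fdr = 0.2) {
  if (is(x, "LncCountExperiment")) {
    if (is.null(sheet)) sheet <- sampleSheet(x)
    x <- countsMatrix(x)
  }
  .nbLRT(x, sheet, norm, phi, minExpressedSamples, paired = TRUE, fdr = fdr)
}

#' Unpaired (two-group) negative-binomial likelihood-ratio test
#'
#' The confirmation-cohort test: identical machinery to [pairedLRT()] but
#' with an intercept + condition full model against an intercept-only
#' reduced model, for unpaired tumor/normal cohorts.
#'
#' @inheritParams pairedLRT
#' @return A [DEResultSet-class].
#' @examples
#' cfg <- simulationConfig(nFeatures = 200, nTrueDE = 10, nTumorConfirm = 30,
#'                         nNormalConfirm = 10, seed = 2)
#' sim <- simulateDiscoveryCohort(cfg)
#' conf <- simulateConfirmationCohort(cfg, sim$truth)
#' groupLRT(conf, fdr = 0.05)
#' @export
groupLRT <- function(x, sheet = NULL, norm = NULL, phi = NULL,
                     minExpressedSamples = 2L, fdr = 0.05) {
  if (is(x, "LncCountExperiment")) {
    if (is.null(sheet)) sheet <- sampleSheet(x)
    x <- countsMatrix(x)
  }
  .nbLRT(x, sheet, norm, phi, minExpressedSamples, paired = FALSE, fdr = fdr)
}
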