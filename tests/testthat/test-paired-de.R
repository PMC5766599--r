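# Shared small paired dataset for several blocks
makePairedToy <- function(seed = 21, nFeatures = 50, nPairs = 3,
                          mu = 30, phi = 0.1, lfc = rep(0, nFeatures)) {
  set.seed(seed)
  patient <- rep(sprintf("P%d", seq_len(nPairs)), 2)
  cond <- rep(c("tumor", "normal"), each = nPairs)
  m <- matrix(rnbinom(nFeatures * 2 * nPairs,
                      mu = exp(log(mu) + outer(lfc * log(2),
                                               as.numeric(cond == "tumor"))),
                      size = 1 / phi),
              nFeatures, 2 * nPairs,
              dimnames = list(sprintf("f%03d", seq_len(nFeatures)),
                              paste0(patient, "_", substr(cond, 1, 1))))
  sheet <- data.frame(sample_id = colnames(m), patient_id = patient,
                      condition = cond, stage = NA_character_)
  list(counts = m, sheet = sheet)
}

test_that("Poisson intercept-only fit recovers the arithmetic mean", {
  y <- c(4, 9)
  fit <- fitNbGlm(y, design = matrix(1, 2, 1), offset = c(0, 0), phi = 0)
  expect_equal(unname(exp(fit$beta[1])), mean(y), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("an all-zero feature is flagged, not fitted", {
  fit <- fitNbGlm(rep(0, 4), design = matrix(1, 4, 1), offset = rep(0, 4),
                  phi = 0.1)
  expect_false(fit$converged)
  expect_equal(fit$loglik, 0)
})

test_that("IRLS log-likelihood matches the brute-force grid oracle", {
  toy <- makePairedToy(seed = 8, nFeatures = 20, mu = 25, phi = 0.1)
  sheet <- toy$sheet
  X <- stats::model.matrix(~ factor(sheet$patient_id) +
                             factor(sheet$condition, c("normal", "tumor")))
  off <- rep(log(1e4), ncol(toy$counts))
  for (g in seq_len(20)) {
    y <- toy$counts[g, ]
    fit <- fitNbGlm(y, X, off, phi = 0.1)
    oracle <- gridMaxNbLoglik(y, X, off, phi = 0.1)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    expect_gte(fit$loglik, oracle$loglik - 1e-4)
  }
})

test_that("common dispersion estimation brackets the truth", {
  # Poisson data: estimate collapses to the lower boundary
  sim <- simulateDiscoveryCohort(
    simulationConfig(nFeatures = 2000L, nTrueDE = 0L, dispersion = 0,
                     pcgMeanCount = 100, lncMeanCount = 20,
                     patientEffectSd = 0.3, seed = 31L))
  expect_lte(estimateCommonDispersion(sim$experiment), 0.01)

  # NB data with phi = 0.4, n = 3 pairs: wide but informative band
  sim <- simulateDiscoveryCohort(
    simulationConfig(nFeatures = 2000L, nTrueDE = 0L, dispersion = 0.4,
                     pcgMeanCount = 100, lncMeanCount = 20,
                     patientEffectSd = 0.3, seed = 32L))
  phi <- estimateCommonDispersion(sim$experiment)
  expect_gte(phi, 0.25)
  expect_lte(phi, 0.6)
})

test_that("constant features are excluded from dispersion estimation with a message", {
  toy <- makePairedToy(seed = 4, nFeatures = 30)
  toy$counts[1, ] <- 7L
  expect_message(estimateCommonDispersion(toy$counts, toy$sheet),
                 "identical counts")
})

test_that("dispersion and p-values track an independent NB GLM implementation", {
  skip_if_not_installed("edgeR")
  toy <- makePairedToy(seed = 12, nFeatures = 300, mu = 50, phi = 0.2,
                       lfc = c(rep(3, 15), rep(0, 285)))
  de <- pairedLRT(toy$counts, toy$sheet)
  r <- deResults(de)

  y <- edgeR::DGEList(toy$counts)
  y <- edgeR::calcNormFactors(y)
  design <- stats::model.matrix(~ factor(toy$sheet$patient_id) +
                                  factor(toy$sheet$condition,
                                         c("normal", "tumor")))
  y <- edgeR::estimateGLMCommonDisp(y, design)
  fit <- edgeR::glmFit(y, design, dispersion = y$common.dispersion)
  lrt <- edgeR::glmLRT(fit)

  expect_equal(dispersionEstimate(de), y$common.dispersion, tolerance = 0.3)
  expect_gt(cor(r$p_value, lrt$table$PValue, method = "spearman",
                use = "complete.obs"), 0.99)
  expect_gt(cor(r$log2FC, lrt$table$logFC, use = "complete.obs"), 0.99)
})

test_that("a feature identical across conditions gives statistic 0 and p 1", {
  toy <- makePairedToy(seed = 5, nFeatures = 20)
  toy$counts[3, ] <- rep(c(11L, 25L, 40L), 2)  # tumor == normal per patient
  eq <- data.frame(sample_id = toy$sheet$sample_id, lib_size = 1e4,
                   norm_factor = 1, eff_lib_size = 1e4)
  de <- pairedLRT(toy$counts, toy$sheet, norm = eq, phi = 0.1)
  r <- deResults(de)
  expect_equal(r$lrt_stat[3], 0, tolerance = 1e-6)
  expect_equal(r$p_value[3], 1, tolerance = 1e-5)
})

test_that("swapping tumor and normal labels negates log2FC and keeps p-values", {
  toy <- makePairedToy(seed = 6, nFeatures = 80, phi = 0.15,
                       lfc = c(rep(2, 5), rep(0, 75)))
  de1 <- pairedLRT(toy$counts, toy$sheet, phi = 0.15)
  flipped <- toy$sheet
  flipped$condition <- ifelse(flipped$condition == "tumor", "normal", "tumor")
  de2 <- pairedLRT(toy$counts, flipped, phi = 0.15)
  r1 <- deResults(de1); r2 <- deResults(de2)
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-5)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
})

test_that("a depth change in one sample barely moves log2FC when normalized", {
  toy <- makePairedToy(seed = 7, nFeatures = 1200, mu = 200, phi = 0.05,
                       lfc = c(rep(3, 10), rep(0, 1190)))
  de1 <- pairedLRT(toy$counts, toy$sheet, phi = 0.1)
  scaled <- toy$counts
  scaled[, 2] <- scaled[, 2] * 4L
  de2 <- pairedLRT(scaled, toy$sheet, phi = 0.1)
  dif <- abs(deResults(de1)$log2FC - deResults(de2)$log2FC)
  expect_lt(max(dif, na.rm = TRUE), 0.05)
})

test_that("low-count filtering reports untested features instead of dropping them", {
  toy <- makePairedToy(seed = 9, nFeatures = 20)
  toy$counts[2, ] <- c(0L, 0L, 0L, 0L, 0L, 3L)  # expressed in 1 sample
  de <- pairedLRT(toy$counts, toy$sheet, phi = 0.1, minExpressedSamples = 2)
  r <- deResults(de)
  expect_equal(nrow(r), 20L)
  expect_false(r$tested[2])
  expect_true(is.na(r$p_value[2]))
})

test_that("BH adjustment matches its closed form and stats::p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    p[sample(length(p), 1)] <- NA
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
    expect_true(all(bhAdjust(p) >= p, na.rm = TRUE))
  }
  # monotone step function of input p
  p <- sort(runif(30))
  adj <- bhAdjust(p)
  expect_true(all(diff(adj) >= -1e-12))
})

test_that("planted low-abundance effects are recovered with bounded bias", {
  # 500 lncRNA-like features (mean 5 reads) with log2FC = 4, embedded in a
  # background of 2000 null protein-coding features that anchor normalization
  toy <- makePairedToy(seed = 77, nFeatures = 2500, mu = 1, phi = 0.2,
                       lfc = c(rep(4, 500), rep(0, 2000)))
  set.seed(78)
  mu <- c(rep(5, 500), rep(200, 2000))
  cond <- as.numeric(toy$sheet$condition == "tumor")
  muMat <- outer(mu, rep(1, 6)) *
    2^outer(c(rep(4, 500), rep(0, 2000)), cond)
  toy$counts[] <- rnbinom(length(muMat), mu = muMat, size = 1 / 0.2)
  de <- pairedLRT(toy$counts, toy$sheet)
  est <- deResults(de)$log2FC[1:500]
  expect_lte(abs(median(est, na.rm = TRUE) - 4), 1.0)
})
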