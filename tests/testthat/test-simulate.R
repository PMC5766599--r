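test_that("generators are deterministic under a fixed seed", {
  cfg <- tinyConfig()
  a <- simulateDiscoveryCohort(cfg)
  b <- simulateDiscoveryCohort(cfg)
  expect_identical(countsMatrix(a$experiment), countsMatrix(b$experiment))
  expect_identical(a$truth, b$truth)
  expect_identical(countsMatrix(simulateConfirmationCohort(cfg, a$truth)),
                   countsMatrix(simulateConfirmationCohort(cfg, b$truth)))
  expect_identical(simulateQpcrCohort(15, effectDeltaCt = 1, seed = 9),
                   simulateQpcrCohort(15, effectDeltaCt = 1, seed = 9))
})

test_that("invalid configuration names the offending field", {
  expect_error(simulationConfig(fracLncRNA = 1.4), "fracLncRNA")
  expect_error(simulationConfig(nFeatures = 10, nTrueDE = 11), "nTrueDE")
  expect_error(simulationConfig(dispersion = -1), "dispersion")
  expect_error(simulationConfig(logfcRange = c(3, Inf)), "logfcRange")
})

test_that("no planted signal means an all-null truth table", {
  sim <- simulateDiscoveryCohort(tinyConfig(nTrueDE = 0L))
  expect_false(any(sim$truth$is_de))
  expect_identical(sim$truth$true_log2fc, rep(0, 200))
})

test_that("normal-condition counts match the configured baseline mean in the Poisson limit", {
  cfg <- simulationConfig(nFeatures = 10000L, fracLncRNA = 0, nTrueDE = 0L,
                          pcgMeanCount = 100, dispersion = 0,
                          patientEffectSd = 0, libsizeVariation = FALSE,
                          seed = 5L)
  sim <- simulateDiscoveryCohort(cfg)
  sheet <- sampleSheet(sim$experiment)
  normals <- countsMatrix(sim$experiment)[, sheet$condition == "normal"]
  se <- sqrt(100 / ncol(normals))            # Poisson: var = mu
  within3 <- abs(rowMeans(normals) - 100) <= 3 * se
  expect_gt(mean(within3), 0.99)
  expect_lt(abs(mean(normals) - 100), 0.5)
})

test_that("counts are overdispersed when phi > 0 and lncRNA fraction is honoured", {
  cfg <- simulationConfig(nFeatures = 1500L, fracLncRNA = 0.35, nTrueDE = 0L,
                          nPairsDiscovery = 10L, pcgMeanCount = 50,
                          lncMeanCount = 50, dispersion = 0.4,
                          patientEffectSd = 0, libsizeVariation = FALSE,
                          seed = 6L)
  sim <- simulateDiscoveryCohort(cfg)
  cnt <- countsMatrix(sim$experiment)
  vars <- apply(cnt, 1, var)
  means <- rowMeans(cnt)
  # NB with mu = 50, phi = 0.4: var = mu + phi mu^2 = 1050 >> mu
  expect_gt(mean(vars) / mean(means), 5)
  expect_gt(mean(vars > means), 0.9)
  expect_equal(sum(featureAnnotation(sim$experiment)$is_lncRNA),
               round(0.35 * 1500))
})

test_that("confirmation cohort carries concordant effects and the latent factor", {
  cfg <- tinyConfig(nTumorConfirm = 200L, nNormalConfirm = 20L,
                    latentFactorLoading = 1, plantedSetSize = 30L)
  sim <- simulateDiscoveryCohort(cfg)
  conf <- simulateConfirmationCohort(cfg, sim$truth)
  cnt <- countsMatrix(conf)
  sheet <- sampleSheet(conf)
  tum <- sheet$condition == "tumor"

  de <- sim$truth[sim$truth$is_de, ]
  obsLfc <- log2((rowMeans(cnt[de$feature_id, !tum]) + 0.5) /
                   (rowMeans(cnt[de$feature_id, tum]) + 0.5))
  expect_true(all(sign(-obsLfc) == sign(de$true_log2fc)))

  target <- sim$truth$feature_id[sim$truth$is_target]
  lcpm <- log2(cnt + 0.5)
  rSet <- cor(lcpm[target, tum],
              t(lcpm[sim$truth$in_planted_set, tum, drop = FALSE]))
  bg <- !sim$truth$in_planted_set & !sim$truth$is_target
  rBg <- cor(lcpm[target, tum], t(lcpm[bg, tum, drop = FALSE]))
  expect_gt(mean(rSet), mean(rBg, na.rm = TRUE))
  expect_gt(mean(rSet), 0.3)
})

test_that("zero latent loading leaves planted-set correlations centred on zero", {
  cfg <- tinyConfig(nTumorConfirm = 300L, nNormalConfirm = 20L,
                    latentFactorLoading = 0, plantedSetSize = 50L,
                    pcgMeanCount = 100, seed = 17L)
  sim <- simulateDiscoveryCohort(cfg)
  conf <- simulateConfirmationCohort(cfg, sim$truth)
  cnt <- countsMatrix(conf)
  tum <- sampleSheet(conf)$condition == "tumor"
  target <- sim$truth$feature_id[sim$truth$is_target]
  lcpm <- log2(cnt + 0.5)
  rSet <- cor(lcpm[target, tum],
              t(lcpm[sim$truth$in_planted_set, tum, drop = FALSE]))
  expect_lt(mean(abs(rSet)), 3 / sqrt(300))
})

test_that("qPCR generator honours the delta-Ct effect exactly when noiseless", {
  tab0 <- simulateQpcrCohort(12, effectDeltaCt = 0, noiseSd = 0, seed = 3)
  rec0 <- qpcrRecords(tab0)
  tum <- rec0[rec0$tissue == "tumor", ]
  nor <- rec0[rec0$tissue == "normal", ]
  expect_equal(tum$rel_expr,
               nor$rel_expr[match(tum$patient_id, nor$patient_id)])

  tab1 <- simulateQpcrCohort(12, effectDeltaCt = 1, noiseSd = 0, seed = 3)
  rec1 <- qpcrRecords(tab1)
  tum <- rec1[rec1$tissue == "tumor", ]
  nor <- rec1[rec1$tissue == "normal", ]
  expect_equal(tum$rel_expr,
               2 * nor$rel_expr[match(tum$patient_id, nor$patient_id)])

  expect_error(simulateQpcrCohort(10, noiseSd = -0.1), "noiseSd")
})

test_that("a planted qPCR effect is detected by the paired signed-rank test", {
  # effect 1 cycle, noise 0.5, 139 pairs: p < 0.001 in nearly every replicate
  hits <- vapply(1:20, function(s) {
    tab <- simulateQpcrCohort(139, effectDeltaCt = 1, noiseSd = 0.5, seed = s)
    qpcrPairedTest(qpcrRecords(tab))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
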