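test_that("relative expression follows the 2^-deltaCt closed form", {
  expect_equal(relativeExpression(20, 20), 1)
  expect_equal(relativeExpression(25, 20), 0.03125)
  expect_true(is.na(relativeExpression(NA, 20)))
  # strictly decreasing in target Ct, increasing in reference Ct
  expect_true(relativeExpression(24, 20) > relativeExpression(25, 20))
  expect_true(relativeExpression(25, 21) > relativeExpression(25, 20))
})

test_that("duplicate wells are averaged on the Ct scale", {
  tab <- data.frame(patient_id = "p1", tissue = "tumor", stage = "II",
                    target = "t", ct_rep1 = 24.9, ct_rep2 = 25.1,
                    ref_ct_rep1 = 20, ref_ct_rep2 = 20)
  rec <- qpcrRecords(tab)
  expect_equal(rec$ct_target, 25)
  expect_equal(rec$rel_expr, 2^-5)
})

test_that("signed-rank p-values match full enumeration for n <= 10", {
  # all-positive n = 6: the textbook 2/2^6
  res <- wilcoxonSignedRank(c(0.5, 1.1, 0.2, 2, 0.9, 1.4))
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$method, "exact")
  # a single pair can never reach significance two-sided
  expect_equal(wilcoxonSignedRank(3.2)$p_value, 1)

  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    ours <- wilcoxonSignedRank(d)
    oracle <- wilcoxonExactOracle(d)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-12)
  }
})

test_that("exact and approximate signed-rank p agree at the switchover", {
  set.seed(12)
  d <- rnorm(25, 0.35, 1)
  pExact <- wilcoxonSignedRank(d, exactLimit = 25)$p_value
  pApprox <- wilcoxonSignedRank(d, exactLimit = 10)$p_value
  expect_lt(abs(pExact - pApprox), 0.01)
})

test_that("degenerate signed-rank inputs are handled explicitly", {
  expect_warning(res <- wilcoxonSignedRank(c(0, 0, 0)), "zero")
  expect_equal(res$p_value, 1)
  # ties in |d| get midranks and still match base R's exact test when tie-free
  res <- wilcoxonSignedRank(c(1, -1, 2, 2, -3))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("Kruskal-Wallis matches stats::kruskal.test including ties", {
  set.seed(13)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    g <- rep(seq_len(k), times = sample(3:10, k, replace = TRUE))
    v <- round(rnorm(length(g)), 1)          # rounding induces ties
    ours <- kruskalWallis(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  allEq <- kruskalWallis(rep(2, 9), rep(1:3, 3))
  expect_equal(allEq$statistic, 0)
  expect_equal(allEq$p_value, 1)
  expect_error(kruskalWallis(1:5, rep("a", 5)), "2 groups")
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum normal approximation", {
  set.seed(14)
  v <- c(rnorm(30), rnorm(30, 0.6))
  g <- rep(c("a", "b"), each = 30)
  kw <- kruskalWallis(v, g)
  z <- pairZOracle(v[1:30], v[31:60])
  pWil <- 2 * pnorm(-abs(z))
  expect_lt(abs(kw$p_value - pWil), 0.02)
})

test_that("Steel-Dwass reduces to the rank-sum test for two groups", {
  set.seed(15)
  a <- rnorm(10); b <- rnorm(12, 0.8)
  sd2 <- steelDwass(c(a, b), rep(c("a", "b"), c(10, 12)))
  pWil <- 2 * pnorm(-abs(pairZOracle(a, b)))
  expect_equal(sd2$p_value, pWil, tolerance = 1e-6)
})

test_that("Steel-Dwass handles identical groups and validates input", {
  v <- rep(c(3, 3, 3), 3)
  sd3 <- steelDwass(v, rep(c("a", "b", "c"), each = 3))
  expect_equal(sd3$p_value, rep(1, 3))
  expect_error(steelDwass(1:4, c("a", "a", "b", "c")), "at least 2")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(16)
  v <- rexp(24) + 0.1
  g <- rep(c("a", "b", "c"), each = 8)
  expect_equal(kruskalWallis(v, g)$p_value, kruskalWallis(log(v), g)$p_value)
  expect_equal(steelDwass(v, g)$p_value, steelDwass(log(v), g)$p_value)
  d <- rlnorm(12)
  r1 <- wilcoxonSignedRank(d - 1)
  # signed-rank needs a shift-free monotone map of the differences' signs:
  # scaling preserves signs and |d| order
  r2 <- wilcoxonSignedRank(3 * (d - 1))
  expect_equal(r1$p_value, r2$p_value)
})

test_that("stagewise analysis flags a planted stage contrast", {
  flagged <- vapply(1:20, function(s) {
    tab <- simulateQpcrCohort(
      150, stageDistribution = c(CA = 10, I = 20, II = 30, III = 45, IV = 45),
      effectDeltaCt = 1, noiseSd = 0.5, seed = s,
      stageEffects = c(III = 1.5))
    res <- stagewiseAnalysis(qpcrRecords(tab))[[1]]
    if (is.null(res$pairwise)) return(FALSE)
    row <- res$pairwise[res$pairwise$group1 == "III" &
                          res$pairwise$group2 == "IV", ]
    nrow(row) == 1 && row$p_value < 0.05
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
})

test_that("stagewise analysis stays quiet without a planted effect", {
  flaggedPairs <- vapply(1:25, function(s) {
    tab <- simulateQpcrCohort(
      100, stageDistribution = c(CA = 20, I = 20, II = 20, III = 20, IV = 20),
      effectDeltaCt = 1, noiseSd = 0.5, seed = 1000 + s)
    res <- stagewiseAnalysis(qpcrRecords(tab))[[1]]
    if (is.null(res$pairwise)) return(0L)
    sum(res$pairwise$p_value < 0.05)
  }, integer(1))
  # family-wise control: significant pairs are rare under the null
  expect_lte(mean(flaggedPairs > 0), 0.15)
})

test_that("a single-stage cohort surfaces the Kruskal-Wallis error cleanly", {
  tab <- simulateQpcrCohort(10, stageDistribution = c(II = 10),
                            effectDeltaCt = 1, noiseSd = 0.5, seed = 4)
  expect_error(stagewiseAnalysis(qpcrRecords(tab)), "2 groups")
})
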