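randomCorr <- function(nL, nP, seed) {
  set.seed(seed)
  matrix(runif(nL * nP, -1, 1), nL, nP,
         dimnames = list(sprintf("l%02d", seq_len(nL)),
                         sprintf("g%02d", seq_len(nP))))
}

test_that("edge selection obeys the ceiling rule per sign", {
  corr <- randomCorr(20, 50, 30)       # P = 1000
  e <- selectEdges(corr, 0.005)
  expect_equal(sum(e$sign == "positive"), 5L)
  expect_equal(sum(e$sign == "negative"), 5L)

  corr <- randomCorr(10, 10, 31)       # P = 100: ceil(0.5) = 1
  e <- selectEdges(corr, 0.005)
  expect_equal(table(e$sign)[["positive"]], 1L)
  expect_equal(table(e$sign)[["negative"]], 1L)

  expect_error(selectEdges(corr, 0), "edgeFraction")
  expect_error(selectEdges(corr, 0.6), "edgeFraction")
})

test_that("edge selection matches the full-sort oracle on random matrices", {
  for (s in 1:50) {
    corr <- randomCorr(sample(3:12, 1), sample(3:15, 1), 100 + s)
    if (s %% 3 == 0) corr[sample(length(corr), 5)] <- NA
    frac <- sample(c(0.005, 0.05, 0.2), 1)
    ours <- selectEdges(corr, frac)
    oracle <- selectEdgesOracle(corr, frac)
    ourPos <- ours[ours$sign == "positive", c("lnc_id", "pcg_id", "r")]
    ourNeg <- ours[ours$sign == "negative", c("lnc_id", "pcg_id", "r")]
    rownames(ourPos) <- rownames(ourNeg) <- NULL
    oraclePos <- oracle$pos; rownames(oraclePos) <- NULL
    oracleNeg <- oracle$neg; rownames(oracleNeg) <- NULL
    expect_equal(ourPos, oraclePos[, c("lnc_id", "pcg_id", "r")])
    expect_equal(ourNeg, oracleNeg[, c("lnc_id", "pcg_id", "r")])
  }
})

test_that("vertex selection is monotone in the thresholds and annotation-aware", {
  d <- data.frame(feature_id = c("l1", "l2", "g1", "g2", "x1"),
                  log2FC = c(3, -4, 2, -2, 1),
                  fdr = c(0.01, 0.15, 0.05, 0.19, 0.01))
  cf <- data.frame(feature_id = c("l1", "l2", "g1", "g2", "x1"),
                   log2FC = c(2, -3, 1, -1, 1),
                   fdr = c(0.001, 0.04, 0.2, 0.01, 0.001))
  ann <- data.frame(feature_id = c("l1", "l2", "g1", "g2"),
                    symbol = c("l1", "l2", "g1", "g2"),
                    biotype = c("lincRNA", "antisense", "protein_coding",
                                "protein_coding"),
                    is_lncRNA = c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(v <- selectVertices(d, cf, ann), "lacking annotation")
  expect_setequal(v$lncRNA, c("l1", "l2"))
  expect_setequal(v$protein_coding, "g2")    # g1 fails the confirmation FDR
  suppressWarnings({
    tight <- selectVertices(d, cf, ann, fdrConf = 0.01)
    expect_true(all(tight$lncRNA %in% v$lncRNA))
    none <- selectVertices(d, cf[0, ], ann)
  })
  expect_equal(lengths(none), c(lncRNA = 0L, protein_coding = 0L))
})

test_that("the built network is bipartite and deterministic under relabeling", {
  cfg <- tinyConfig(nFeatures = 300L, nTrueDE = 30L, nTumorConfirm = 120L,
                    nNormalConfirm = 12L, plantedSetSize = 15L)
  sim <- simulateDiscoveryCohort(cfg)
  conf <- simulateConfirmationCohort(cfg, sim$truth)
  truth <- sim$truth
  verts <- list(
    lncRNA = truth$feature_id[truth$is_lncRNA & truth$is_de],
    protein_coding = truth$feature_id[!truth$is_lncRNA & truth$is_de])
  net <- buildNetwork(conf, verts, edgeFraction = 0.02)
  e <- networkEdges(net)
  v <- networkVertices(net)
  expect_true(all(e$lnc_id %in% truth$feature_id[truth$is_lncRNA]))
  expect_true(all(e$pcg_id %in% truth$feature_id[!truth$is_lncRNA]))
  expect_lte(nrow(e), 2 * ceiling(0.02 * networkParams(net)$n_pairs_defined))
  expect_true(all(v$degree > 0))   # isolated vertices dropped by default

  # permuting sample order leaves the network unchanged
  cnt <- countsMatrix(conf)
  perm <- sample(ncol(cnt))
  net2 <- buildNetwork(cnt[, perm], verts, edgeFraction = 0.02,
                       sheet = sampleSheet(conf)[perm, ])
  expect_equal(networkEdges(net2), e)
})

test_that("the latent factor pulls planted genes into the target lncRNA's positive edges", {
  cfg <- tinyConfig(nFeatures = 400L, nTrueDE = 60L, nTumorConfirm = 200L,
                    nNormalConfirm = 15L, plantedSetSize = 30L,
                    latentFactorLoading = 1.2, seed = 55L)
  sim <- simulateDiscoveryCohort(cfg)
  conf <- simulateConfirmationCohort(cfg, sim$truth)
  truth <- sim$truth
  verts <- list(
    lncRNA = unique(c(truth$feature_id[truth$is_lncRNA & truth$is_de],
                      truth$feature_id[truth$is_target])),
    protein_coding = truth$feature_id[!truth$is_lncRNA])
  net <- buildNetwork(conf, verts, edgeFraction = 0.01)
  e <- networkEdges(net)
  target <- truth$feature_id[truth$is_target]
  posTarget <- e$pcg_id[e$lnc_id == target & e$sign == "positive"]
  expect_gt(length(posTarget), 0)
  planted <- truth$feature_id[truth$in_planted_set]
  nPcg <- sum(!truth$is_lncRNA)
  pHyper <- phyper(sum(posTarget %in% planted) - 1, length(planted),
                   nPcg - length(planted), length(posTarget),
                   lower.tail = FALSE)
  expect_lt(pHyper, 0.01)
})

test_that("hub report ranks degree, splits signs and computes Jaccard overlaps", {
  e <- data.frame(
    lnc_id = c(rep("hubA", 5), rep("hubB", 3)),
    pcg_id = c(paste0("g", 1:5), paste0("g", c(1, 2, 9))),
    r = c(rep(0.9, 4), -0.8, 0.7, 0.7, -0.6),
    sign = c(rep("positive", 4), "negative", "positive", "positive",
             "negative"))
  v <- data.frame(
    feature_id = c("hubA", "hubB", paste0("g", c(1:5, 9))),
    class = c("lncRNA", "lncRNA", rep("protein_coding", 6)),
    degree = c(5L, 3L, 2L, 2L, 1L, 1L, 1L, 1L))
  net <- new("CoexpressionNetwork", vertices = v, edges = e,
             params = list(edge_fraction = 0.1, sample_subset = "tumor",
                           n_pairs_defined = 12L))
  rep_df <- hubReport(net)
  expect_equal(rep_df$feature_id, c("hubA", "hubB"))
  expect_equal(rep_df$degree, c(5L, 3L))
  expect_equal(rep_df$n_positive, c(4L, 2L))
  expect_equal(rep_df$n_negative, c(1L, 1L))
  expect_equal(rep_df$jaccard_vs_top[1], 1)
  # brute force: |{g1,g2,g9} ∩ {g1..g5}| / |union| = 2 / 6
  expect_equal(rep_df$jaccard_vs_top[2], 2 / 6)

  empty <- new("CoexpressionNetwork",
               vertices = data.frame(feature_id = character(),
                                     class = character(),
                                     degree = integer()),
               edges = data.frame(lnc_id = character(),
                                  pcg_id = character(), r = numeric(),
                                  sign = character()),
               params = list())
  expect_equal(nrow(hubReport(empty)), 0L)
})

test_that("network writers emit SIF, GraphML and a round-trippable edge list", {
  e <- data.frame(lnc_id = c("l1", "l1"), pcg_id = c("g1", "g2"),
                  r = c(0.9, -0.8), sign = c("positive", "negative"))
  v <- data.frame(feature_id = c("l1", "g1", "g2"),
                  class = c("lncRNA", "protein_coding", "protein_coding"),
                  degree = c(2L, 1L, 1L))
  net <- new("CoexpressionNetwork", vertices = v, edges = e,
             params = list(edge_fraction = 0.1, sample_subset = "tumor",
                           n_pairs_defined = 2L))
  sif <- withr::local_tempfile(fileext = ".sif")
  writeSif(net, sif)
  expect_equal(readLines(sif),
               c("l1\tcoexpr_pos\tg1", "l1\tcoexpr_neg\tg2"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(net, tsv)
  rt <- read.delim(tsv)
  expect_equal(rt$r, e$r)
})
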