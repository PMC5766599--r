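#' @include AllGenerics.R enrichment.R confirm.R
NULL

#' Select network vertices from dual-cohort DE results
#'
#' Candidate vertices of the co-expression network are features passing
#' both cohorts' strict FDR thresholds (discovery < `fdrDisc`,
#' confirmation < `fdrConf`), split into lncRNA and protein-coding classes
#' by the annotation. Features without an annotation row are excluded with
#' a warning.
#'
#' @param discovery,confirmation [DEResultSet-class] or result data frames
#' @param annotation annotation `data.frame` (`feature_id`, `biotype`,
#'   `is_lncRNA`)
#' @param fdrDisc,fdrConf strict FDR thresholds
#' @return A list with character vectors `lncRNA` and `protein_coding`.
#' @examples
#' disc <- data.frame(feature_id = c("l1", "g1"), log2FC = c(3, -4),
#'                    fdr = c(0.01, 0.02))
#' conf <- data.frame(feature_id = c("l1", "g1"), log2FC = c(2, -3),
#'                    fdr = c(0.001, 0.002))
#' ann <- data.frame(feature_id = c("l1", "g1"), symbol = c("l1", "g1"),
#'                   biotype = c("lincRNA", "protein_coding"),
#'                   is_lncRNA = c(TRUE, FALSE))
#' selectVertices(disc, conf, ann)
#' @export
selectVertices <- function(discovery, confirmation, annotation,
                           fdrConf = 0.05, fdrDisc = 0.2) {
  hits <- confirmHits(discovery, confirmation, fdrDisc = fdrDisc,
                      fdrConf = fdrConf, requireDirectionMatch = FALSE)
  j <- match(hits$feature_id, annotation$feature_id)
  if (anyNA(j)) {
    warning(sum(is.na(j)), " vertex candidate(s) lacking annotation excluded")
    hits <- hits[!is.na(j), , drop = FALSE]
    j <- j[!is.na(j)]
  }
  isLnc <- annotation$is_lncRNA[j]
  list(lncRNA = hits$feature_id[isLnc],
       protein_coding = hits$feature_id[!isLnc &
                          annotation$biotype[j] == "protein_coding"])
}

#' Percentile-threshold edge selection
#'
#' From a lncRNA-by-protein-coding correlation matrix, selects the
#' `ceil(edgeFraction * P)` most positive correlations as positive edges
#' and the `ceil(edgeFraction * P)` most negative as negative edges, where
#' `P` is the number of defined (non-missing) pairs. The percentile is
#' taken over signed r, not |r|. Ties at the cutoff are broken by
#' (lncRNA id, protein-coding id) lexicographic order, so the edge list is
#' deterministic.
#'
#' @param corr numeric matrix, rows = lncRNA ids, columns = protein-coding
#'   ids; `NA` entries (undefined correlations) are excluded from the pool
#' @param edgeFraction fraction in (0, 0.5] selected per sign
#' @return A `data.frame` with columns `lnc_id`, `pcg_id`, `r`, `sign`.
#' @examples
#' m <- matrix(seq(-1, 1, length.out = 12), 3, 4,
#'             dimnames = list(paste0("l", 1:3), paste0("g", 1:4)))
#' selectEdges(m, 0.1)
#' @export
selectEdges <- function(corr, edgeFraction = 0.005) {
  if (edgeFraction <= 0 || edgeFraction > 0.5)
    stop("edgeFraction must lie in (0, 0.5]")
  df <- data.frame(lnc_id = rep(rownames(corr), ncol(corr)),
                   pcg_id = rep(colnames(corr), each = nrow(corr)),
                   r = as.vector(corr))
  df <- df[!is.na(df$r), , drop = FALSE]
  P <- nrow(df)
  if (P == 0L)
    return(data.frame(lnc_id = character(), pcg_id = character(),
                      r = numeric(), sign = character()))
  nSel <- ceiling(edgeFraction * P)
  pos <- df[order(-df$r, df$lnc_id, df$pcg_id, method = "radix"), ][seq_len(nSel), ]
  neg <- df[order(df$r, df$lnc_id, df$pcg_id, method = "radix"), ][seq_len(nSel), ]
  pos$sign <- "positive"
  neg$sign <- "negative"
  out <- rbind(pos, neg)
  out <- out[!duplicated(out[, c("lnc_id", "pcg_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bipartite lncRNA-mRNA co-expression network
#'
#' Computes Pearson correlations between every candidate lncRNA vertex and
#' every candidate protein-coding vertex on `log2(CPM + 0.5)` expression
#' over the chosen sample subset (tumor samples by default), then keeps the
#' extreme `edgeFraction` per sign via [selectEdges()]. Vertices left
#' without an edge are dropped by default so the graph matches what would
#' be drawn.
#'
#' @param x [LncCountExperiment-class] or count matrix
#' @param vertices list from [selectVertices()]
#' @param edgeFraction fraction of candidate pairs kept per sign
#' @param sampleSubset `"tumor"` or `"all"`
#' @param keepIsolated keep vertices with no edge?
#' @param sheet sample sheet when `x` is a matrix
#' @return A [CoexpressionNetwork-class].
#' @examples
#' cfg <- simulationConfig(nFeatures = 120, nTumorConfirm = 40,
#'                         nNormalConfirm = 10, seed = 6)
#' sim <- simulateDiscoveryCohort(cfg)
#' conf <- simulateConfirmationCohort(cfg, sim$truth)
#' verts <- list(lncRNA = head(sim$truth$feature_id[sim$truth$is_lncRNA], 5),
#'               protein_coding = head(sim$truth$feature_id[!sim$truth$is_lncRNA], 20))
#' buildNetwork(conf, verts, edgeFraction = 0.05)
#' @export
buildNetwork <- function(x, vertices, edgeFraction = 0.005,
                         sampleSubset = c("tumor", "all"),
                         keepIsolated = FALSE, sheet = NULL) {
  sampleSubset <- match.arg(sampleSubset)
  if (is(x, "LncCountExperiment")) {
    if (is.null(sheet)) sheet <- sampleSheet(x)
    x <- countsMatrix(x)
  }
  samples <- if (sampleSubset == "tumor" && !is.null(sheet))
    sheet$sample_id[sheet$condition == "tumor"] else colnames(x)
  if (length(samples) < 3L) stop("need at least 3 samples in the subset")

  lnc <- intersect(vertices$lncRNA, rownames(x))
  pcg <- intersect(vertices$protein_coding, rownames(x))
  expr <- .logCPM(x)[, samples, drop = FALSE]

  if (length(lnc) && length(pcg)) {
    ## zero-variance rows give NaN from cor(); those pairs leave the pool
    corr <- suppressWarnings(stats::cor(t(expr[lnc, , drop = FALSE]),
                                        t(expr[pcg, , drop = FALSE])))
    corr[!is.finite(corr)] <- NA_real_
    edges <- selectEdges(corr, edgeFraction)
    P <- sum(!is.na(corr))
  } else {
    edges <- data.frame(lnc_id = character(), pcg_id = character(),
                        r = numeric(), sign = character())
    P <- 0L
  }

  vdf <- data.frame(
    feature_id = c(lnc, pcg),
    class = rep(c("lncRNA", "protein_coding"), c(length(lnc), length(pcg))))
  vdf$degree <- vapply(vdf$feature_id, function(id)
    sum(edges$lnc_id == id) + sum(edges$pcg_id == id), integer(1))
  if (!keepIsolated) vdf <- vdf[vdf$degree > 0L, , drop = FALSE]
  rownames(vdf) <- NULL
  new("CoexpressionNetwork", vertices = vdf, edges = edges,
      params = list(edge_fraction = edgeFraction,
                    sample_subset = sampleSubset,
                    n_pairs_defined = P,
                    n_candidate_lnc = length(lnc),
                    n_candidate_pcg = length(pcg)))
}

#' Degree-ranked hub report
#'
#' Ranks lncRNA vertices by degree (ties by id), with per-hub counts of
#' positive and negative edges. When the network has at least two hubs,
#' the Jaccard overlap of each hub's protein-coding neighbor set with the
#' top hub's is included, quantifying shared targets between hubs.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param topK rows to return (default: all lncRNA vertices)
#' @return A `data.frame`: `feature_id`, `degree`, `n_positive`,
#'   `n_negative`, `jaccard_vs_top`.
#' @examples
#' e <- data.frame(lnc_id = "l1", pcg_id = paste0("g", 1:5), r = 0.9,
#'                 sign = "positive")
#' v <- data.frame(feature_id = c("l1", paste0("g", 1:5)),
#'                 class = c("lncRNA", rep("protein_coding", 5)),
#'                 degree = c(5L, rep(1L, 5)))
#' hubReport(new("CoexpressionNetwork", vertices = v, edges = e,
#'               params = list(edge_fraction = 0.1, sample_subset = "tumor",
#'                             n_pairs_defined = 5L)))
#' @export
hubReport <- function(net, topK = Inf) {
  stopifnot(is(net, "CoexpressionNetwork"))
  v <- networkVertices(net)
  e <- networkEdges(net)
  lnc <- v$feature_id[v$class == "lncRNA"]
  if (!length(lnc))
    return(data.frame(feature_id = character(), degree = integer(),
                      n_positive = integer(), n_negative = integer(),
                      jaccard_vs_top = numeric()))
  nb <- lapply(setNames(lnc, lnc), function(id) e$pcg_id[e$lnc_id == id])
  rep_df <- data.frame(
    feature_id = lnc,
    degree = lengths(nb),
    n_positive = vapply(lnc, function(id)
      sum(e$lnc_id == id & e$sign == "positive"), integer(1)),
    n_negative = vapply(lnc, function(id)
      sum(e$lnc_id == id & e$sign == "negative"), integer(1)),
    row.names = NULL)
  rep_df <- rep_df[order(-rep_df$degree, rep_df$feature_id,
                         method = "radix"), , drop = FALSE]
  top <- nb[[rep_df$feature_id[1]]]
  rep_df$jaccard_vs_top <- vapply(rep_df$feature_id, function(id) {
    u <- union(nb[[id]], top)
    if (!length(u)) return(NA_real_)
    length(intersect(nb[[id]], top)) / length(u)
  }, numeric(1))
  rownames(rep_df) <- NULL
  head(rep_df, topK)
}

#' Write a network as SIF, GraphML and an edge-list TSV
#'
#' `writeSif()` writes the Cytoscape simple-interaction format
#' (`lnc coexpr_pos|coexpr_neg pcg`); `writeGraphML()` exports a GraphML
#' graph with vertex `class` and `degree` attributes and edge `r` weights;
#' `writeEdgeList()` writes the plain edge table.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param path output file path
#' @return The path, invisibly.
#' @name networkWriters
NULL

#' @rdname networkWriters
#' @export
writeSif <- function(net, path) {
  e <- networkEdges(net)
  rel <- ifelse(e$sign == "positive", "coexpr_pos", "coexpr_neg")
  writeLines(paste(e$lnc_id, rel, e$pcg_id, sep = "\t"), path)
  invisible(path)
}

#' @rdname networkWriters
#' @export
writeEdgeList <- function(net, path) .writeTsv(networkEdges(net), path)

#' @rdname networkWriters
#' @export
writeGraphML <- function(net, path) {
  v <- networkVertices(net)
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$lnc_id, to = e$pcg_id,
                   r = e$r, sign = e$sign),
    directed = FALSE, vertices = v)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
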