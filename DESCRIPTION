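Package: lncDiscoveR
Title: Paired Negative-Binomial Discovery and Dual-Cohort Confirmation of
    Dysregulated Long Non-Coding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discovering low-abundance long non-coding RNAs
    (lncRNAs) that are dysregulated between tumors and matched normal
    tissue. Implements a paired negative-binomial generalized linear model
    with a likelihood-ratio test (patient-only versus patient+condition),
    trimmed-mean-of-M-values normalization, Cox-Reid common dispersion
    estimation and Benjamini-Hochberg false discovery rate control;
    cross-cohort confirmation with direction concordance and novelty
    annotation; qPCR 2^-deltaCt quantification with Wilcoxon signed-rank,
    Kruskal-Wallis and Steel-Dwass tests; correlation-rank gene-set
    enrichment against a target lncRNA; and percentile-thresholded
    lncRNA-mRNA co-expression network construction. A seeded synthetic-data
    generator reproduces the statistical structure of a small matched
    discovery cohort plus a large unpaired confirmation cohort so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, RNASeq, Normalization,
    NetworkInference, GeneSetEnrichment
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'lncDiscoveR-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'normalize.R'
    'nbglm.R'
    'confirm.R'
    'enrichment.R'
    'io.R'
    'network.R'
    'qpcr.R'
    'simulate.R'
    'pipeline.R'
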