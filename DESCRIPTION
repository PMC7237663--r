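Package: airwaySmoke
Title: Cell-Type-Specific Smoking Response Analysis for Airway Epithelial scRNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting exposure responses in droplet-based
    single-cell RNA-seq of the human airway epithelium. Implements the
    downstream stages of a tracheal-epithelium smoking study as a reusable
    pipeline: cell and gene quality-control filters, depth normalization and
    geometric-mean signature scoring, gated Wilcoxon and latent-covariate
    logistic differential expression, downsampled pairwise marker derivation
    with percentile-based cell characterization, a core/unique/semi-unique
    smoking-response gene taxonomy, smoking-controlled partial Spearman mucin
    co-expression programs, centroid-MST trajectory pseudotime with
    Gaussian-mixture endpoint isolation, donor-level composition statistics,
    and hypergeometric gene-set over-representation. A negative-binomial
    simulator plants recoverable donors, populations, lineages, response
    genes and mucin programs so every stage can be validated without access
    to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
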