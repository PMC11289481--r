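Package: rbsubtype
Title: Methylation Consensus Clustering and Expression Signatures for
    Retinoblastoma Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for DNA methylation-based subtype discovery
    in retinoblastoma and the expression statistics that characterize the
    MYCN-driven subtype. Discretizes array beta-values via a 3-component
    beta-mixture fit with equal-density thresholds, builds a
    multi-algorithm clustering ensemble whose silhouette-filtered runs
    form a thresholded co-clustering graph (final clusters = connected
    components), calls one-vs-rest differential methylation (Welch test,
    Benjamini-Hochberg adjustment, effect and island partitioning),
    derives expression signatures (Storey-Tibshirani q-values with
    bootstrap pi0, Edgington p-value combination, pi-value ranking,
    signature scores as mean log1p tpm, MYCN-knockdown common-response
    set), and correlates local CpG methylation with gene expression. A
    synthetic cohort generator plants the assumed statistical structure so
    every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    cluster,
    kernlab,
    igraph,
    mclust,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
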