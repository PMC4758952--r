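Package: ctdbalance
Title: Promoter-Level Analysis of RNA Polymerase II CTD Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of RNA polymerase II
    C-terminal domain (CTD) modifications from ChIP-seq tag data:
    duplicate filtering, strand-aware promoter and post-TES window
    quantification, Bayesian change-point enrichment segmentation,
    promoter positivity and gene-class assignment (active, polycomb
    repressed, inactive), metagene profiles and promoter heatmaps, the
    K7 methylation/acetylation ratio statistic with tertile
    stratification, and dependency analyses (Spearman and partial
    correlations, exhaustive best-subset regression, cross-validated
    LASSO) linking promoter marks to elongation and mRNA output. A
    seeded synthetic-data generator plants a structural model with a
    negative methylation path to elongation so every stage can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
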