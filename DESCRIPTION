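Package: stagemarker
Title: Stage-Specific Biomarker Discovery from Bulk RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discovering stage-specific candidate
    biomarkers from bulk RNA-seq count data across ordered disease stages
    (adenoma, carcinoma in situ, adenocarcinoma). Implements low-count
    filtering and FPKM normalization, Welch unequal-variance differential
    expression with log2 fold-change thresholds, a from-scratch gene set
    enrichment engine with an absolute (direction-agnostic) ranking mode,
    permutation-based significance and leading-edge extraction, gene-frequency
    prioritization with top-fraction selection, a multi-criterion biomarker
    filter cascade, signature-based immune cell deconvolution by non-negative
    least squares, and 2^-ddCt qPCR fold-change computation. A synthetic-data
    module generates negative-binomial cohorts, gene-set collections and
    immune mixtures with recorded ground truth so every stage of the pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
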