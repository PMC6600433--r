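Package: concordx
Title: Cross-Species Concordant Biomarker Discovery for Nanomaterial
    Exposure Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a cross-species concordant-biomarker
    discovery pipeline for pulmonary nanomaterial (multi-walled carbon
    nanotube) exposure studies. Provides spot-level miRNA microarray
    preprocessing (background subtraction, trim-mean detection thresholds,
    trim-mean normalization, triplicate collapse, detection filtering),
    in vivo differential-expression calling (per-dose two-group ANOVA with
    Benjamini-Hochberg false discovery control and fold-change filtering),
    a from-scratch two-class unpaired Significance Analysis of Microarrays
    (SAM) with permutation null and delta selection at a target FDR,
    in vitro reliability masking, k-nearest-neighbour imputation,
    human-mouse ortholog resolution with seeded tie-breaking, and
    direction-concordance set identification with set-algebra summaries.
    A synthetic-data generator with planted effects makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
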