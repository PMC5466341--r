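Package: paracomp
Title: Paralog-Based Yeast Complementation Analysis of Human Variant
    Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and benchmarking paralog-based yeast
    functional complementation assays of human missense variants. Selects
    human-yeast paralog pairs by disease annotation, essentiality and Pfam
    domain coverage; computes global protein alignments, several percent
    identity definitions and aligned-region classification of variant
    positions; scores spot-dilution complementation assays into a
    semi-quantitative failure-to-complement (FC) score; and evaluates FC
    against computational pathogenicity predictors (PolyPhen-2, PROVEAN)
    with confusion metrics, precision-recall and ROC machinery, exact
    binomial intervals, cross-validated score calibration and score
    combination. Includes a seeded synthetic-data generator so the whole
    pipeline is testable without external downloads, and ships the 35
    variant benchmark table as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
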