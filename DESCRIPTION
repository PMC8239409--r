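Package: coexprot
Title: Protein Co-Expression Network Analysis for Treatment-Control Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for label-free proteomics of treated
    versus control samples: Hi3 (top-3 peptide) protein quantification with
    Occam's-razor protein inference, reference-set median normalization for
    time-course and biopsy designs, signed weighted co-expression network
    construction with topological overlap, hybrid dynamic tree cut module
    detection, eigengene-based module merging and membership (kME) scoring,
    treatment-affected module selection, hypergeometric over-representation
    analysis, cross-dataset integration of weighted proteins, and
    protein-protein interaction hub analysis. Includes a synthetic-data
    generator with planted co-expression modules, intensity-dependent
    missingness, and hub-structured interaction graphs so that every stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
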