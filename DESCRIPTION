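Package: gvunit
Title: Single-Nucleus Transcriptomic Analysis of the Gliovascular Unit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for single-nucleus RNA-seq studies of
    the gliovascular unit in neurodegenerative disease. Implements
    exact-threshold barcode and gene quality control, total-count log
    normalization, conserved cluster-marker and signature-gene calling,
    hypergeometric cell-type assignment against marker reference lists,
    two-part hurdle-model differential expression with likelihood-ratio
    tests, a resampling cluster-ambiguity ("constellation") statistic based
    on repeated random-forest cross-classification, ligand-to-target
    prioritization over a regulation-strength prior matrix, donor-level
    cluster-proportion association tests, DerSimonian-Laird random-effects
    meta-analysis with a dual-endpoint screen, and comparative-CT
    (delta-delta-CT) quantification for qPCR. A synthetic-data module
    generates count matrices, prior regulatory models, cohort effect tables
    and CT tables with planted ground truth so the whole chain is testable
    without restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
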