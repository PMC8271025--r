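Package: radstab
Title: Robustness, Reproducibility and Discriminative Power of Radiomic
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for test-retest stability of radiomic
    features from multi-object phantom MRI experiments. Computes Lin's
    concordance correlation coefficient (CCC) and dynamic range (DR) from
    scan-rescan pairs, intra- and inter-observer intraclass correlation
    coefficients (ICC) from repeated segmentation sessions, selects robust
    and reproducible feature sets per sequence and across sequences, and
    screens pairwise discriminative power with exact Mann-Whitney Gini
    scores and combinatorial significance. Includes a synthetic
    scan-rescan phantom generator with known variance components for
    parameter-recovery validation, and transcribed per-feature stability
    tables for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
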