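Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end two-sample Mendelian randomization (MR) pipeline
    built on GWAS summary statistics: genome-wide instrument selection with
    LD clumping and proxy substitution, allele harmonization with palindromic
    ambiguity handling, instrument-strength (R-squared / F-statistic)
    screening, four causal estimators (inverse-variance weighted, MR-Egger,
    weighted median, weighted mode), pleiotropy diagnostics (MR-PRESSO
    global/outlier/distortion tests, leave-one-out, funnel data), odds-ratio
    reporting with Bonferroni correction over an exposure-by-outcome grid,
    and a calibrated synthetic summary-statistics generator with known
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
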