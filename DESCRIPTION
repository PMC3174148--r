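Package: ppea
Title: Predictive Power Estimation for Transcript-Level Biomarker Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the predictive power of individual transcripts for a
    binary phenotype with an iterative two-way bootstrap: each iteration
    draws a small random gene subset together with a stratified train/test
    sample split, fits a nearest shrunken centroid (PAM) classifier with a
    cross-validated shrinkage threshold, and credits genes that take part
    in models which pass a hold-out error bound. Per-gene sampling and
    success counters yield a predictive-power score and a rank order whose
    stabilisation (Spearman correlation between checkpoints) stops the
    run. Includes the surrounding workflow: informative-transcript
    filtering against vehicle controls, ridit-based labeling of ordered
    histopathology severity, minimal top-n signature construction with
    confusion-matrix metrics, synthetic two-class data generation, and a
    command-line interface.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
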