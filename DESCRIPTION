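Package: switchloop
Title: Binding-Site Switch Classification and Chromatin Loop Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of two-condition regulatory genomics
    experiments in which a signalling change redirects transcription-factor
    occupancy. Implements reproducible-peak filtering by windowed fold
    enrichment, center-distance classification of binding sites into lost,
    switch and de novo classes, motif-stratified overlap with position
    weight matrix scanning, a documented negative-binomial Wald test with
    TPM-based differential-expression calling, Hi-C loop replicate
    reconciliation, and peak-to-loop-anchor-to-TSS connectivity reporting,
    together with synthetic-data generators that plant ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
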