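Package: lcrscan
Title: Detection and Evolutionary Analysis of Protein Low-Complexity Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects low-complexity regions (LCRs) in protein sequences with a
    binomial low-probability-subsequence scanner, profiles their purity,
    composition and position along genes, maps them into codon alignments to
    call orthologous repeats, computes repeat-type diversity statistics
    (richness, accumulation curves, Simpson's and Shannon's indices), and tests
    overlap and co-occurrence between LCRs and positively selected sites using
    Fisher's exact test, together with omega (dN/dS) and GC-content group
    comparisons. Ships a clade-structured synthetic-data generator with full
    ground truth so every pipeline stage can be validated without external
    downloads, and an end-to-end pipeline driver with a machine-readable run
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
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
    vegan,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
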