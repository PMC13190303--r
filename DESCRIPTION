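Package: entryscreen
Title: Phage Host-Factor Screening from Barcoded Transposon Libraries,
    Proximity-Labelling Counts and Homolog Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic screens that identify bacterial host factors
    required for bacteriophage infection. Implements BarSeq barcode extraction
    and counting from amplicon reads, log2-CPM normalization with per-phage
    regression-residual enrichment scoring of barcoded transposon libraries,
    spectral-count enrichment ratios for proximity-labelling and crosslinking
    pull-downs, and homolog-family architecture analytics (global-alignment
    percent identity, greedy dereplication, reference-coordinate identity
    profiles, transmembrane-segment summaries, hydropathy-based segment
    prediction, greedy domain-hit coverage and clade grouping). A synthetic-data
    module simulates every input with machine-readable ground truth, so each
    stage can be exercised end-to-end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
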