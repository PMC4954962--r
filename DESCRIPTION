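Package: inclusionscreen
Title: High-Content Imaging Screen Analysis of Protein Inclusion Formation in Yeast
Version: 0.1.0
Authors@R: person("Screen", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide high-content imaging screens
    of fluorescent protein inclusion (aggregate) formation in Saccharomyces
    cerevisiae. Quantifies inclusion-carrying cells from 16-bit fluorescence
    images by intensity-difference thresholding, calls screen hits with a
    Student's t-test and an expression-level confounder control, performs
    hypergeometric functional-term enrichment against the array-derived gene
    universe, builds physical-interaction hit networks, and scores
    cytotoxicity from optical-density growth curves as generation-time
    prolongation. A seeded synthetic-data generator with planted ground truth
    drives every stage so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
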