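Package: highedges
Title: High-Scoring Interaction Subnetworks from Two-Phenotype Expression Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative causal mechanisms in two-group gene expression
    comparisons by scoring every known gene-gene interaction with a combined
    fold-change/p-value edge score, automatically thresholding the score
    distribution by change-point analysis with a safety margin, and returning
    the resulting high-score subnetwork. Includes KGML/GMT/edge-list readers
    for pathway interaction databases, a moderated t-test front end for
    per-gene statistics, an evaluation harness (over-representation analysis,
    knockout-based true/false positive rates, threshold sweeps scored by
    positive likelihood ratio), and a synthetic knockout-experiment generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    limma,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
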