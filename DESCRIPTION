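Package: masterreg
Title: Master Regulator Discovery from Coexpression Networks with Drug
    Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct transcription-factor-centered regulatory
    networks from a reference expression cohort using mutual information,
    permutation thresholding, bootstrap consensus and data-processing-
    inequality pruning; to nominate master regulators by hypergeometric
    enrichment of regulons with differentially expressed genes across
    case-control studies; to call regulon activation states with two-tail
    gene set enrichment analysis; and to score up/down query signatures
    against a compound signature database with the Kolmogorov-Smirnov
    connectivity statistic for drug repositioning. Includes a synthetic-data
    generator that plants known regulators and drugs so the whole chain is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
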