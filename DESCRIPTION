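Package: ccpromise
Title: Integrated Two-Omics Endpoint Association via Canonical
    Correlation and Projection onto the Most Interesting Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-level integration of two forms of molecular data
    (for example DNA methylation and mRNA expression) with multiple
    clinical endpoints. For each gene, canonical correlation analysis
    summarises the two molecular data blocks into a pair of per-sample
    scores; rank-based association statistics of those scores with each
    endpoint are then projected onto a predefined direction of
    biologically concordant evidence (the PROMISE statistic), and
    significance is assessed with an adaptive, early-stopping
    permutation procedure that shares one permutation stream across all
    statistics of a dataset. Competitor feature-level analyses
    (unadjusted and Bonferroni-adjusted expression or methylation
    PROMISE, and their overlap rules) and a full type-I-error and power
    simulation framework are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
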