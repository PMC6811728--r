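Package: markerpanels
Title: Marker Gene Panel Discovery for Cell Clusters via the XL-mHG Test
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies single- and multi-gene (AND-logic) marker panels that
    isolate a cell cluster from the background in single-cell expression data.
    Implements the XL-mHG minimal-hypergeometric threshold test with an exact
    dynamic-programming p-value, cluster-specific expression binarization with
    a slide-up tie policy, negation tracks for absence markers, exact and
    heuristic enumeration of 2-, 3- and 4-gene panels ranked by hypergeometric
    enrichment and a Cluster Clear Score, Monte Carlo simulation engines
    (Gaussian, negative binomial, and a noisy Poisson-Gamma count model) for
    benchmarking against standard differential-expression tests and
    classifiers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
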