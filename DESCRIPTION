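Package: baldecon
Title: Reference-Based Cell-Type Deconvolution of Bronchoalveolar Lavage
    Methylation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the cell-type composition of mixed-cell DNA
    methylation samples, in particular bronchoalveolar lavage (BAL), by
    constrained least-squares projection onto a reference panel of purified
    cell-type beta profiles (the Houseman approach). Provides detection
    p-value and probe-annotation quality filters, one-vs-rest F-statistic
    signature probe selection ("any" and "both" modes), an exact
    non-negative / simplex-constrained projection solver, validation
    metrics (proportion rescaling, mean squared error, Bland-Altman
    agreement, invariant-probe checks, pooling-variance regression,
    classical MDS), and a synthetic-data generator that simulates pooled
    sorted-cell references and Dirichlet-weighted mixtures with
    beta-distributed measurement noise.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
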