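Package: pcombine
Title: Combining P-Values Across Independent Studies with Gamma-Quantile Tests
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for combining p-values from independent studies into a
    single test of the global null hypothesis: the unweighted and weighted
    z-tests (Stouffer, Mosteller-Bush, square-root-of-n and inverse-standard-
    error weighting), Fisher's method, the Lancaster chi-square-quantile
    generalization, the Chen-Nadarajah one-degree-of-freedom test, general
    gamma-quantile combiners, and an adaptive-shape gamma test that uses the
    inverse of each p-value as its gamma shape parameter with a Monte-Carlo
    empirical null. Includes a type-I-error and power simulation engine for
    two-group normal data with heterogeneous effects, pooled two-proportion
    tests for per-study 2x2 case/control tables, file readers and writers for
    p-value and count tables, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
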