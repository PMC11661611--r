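Package: tumorfdm
Title: Implicit Finite Differences for Fuzzy Time-Fractional Tumor Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the one-dimensional fuzzy time-fractional cancer tumor
    model, a diffusion equation for tumor-cell concentration with a net
    cell-killing term, a Caputo time derivative of order alpha in (0,1], and
    fuzzy (triangular) initial-condition coefficients handled through their
    r-cut endpoints. The time derivative is discretized with the L1 formula
    and space with central differences at the new time level, giving an
    unconditionally stable implicit scheme solved by the Thomas algorithm,
    one tridiagonal system per time step per fuzzy branch. Includes the
    closed-form series benchmark with a time-dependent killing rate, error
    reporting against it, von Neumann amplification-factor checks, Caputo
    L1 weight property checks, and seeded initial-condition perturbation
    experiments. Results are returned as tibbles with tidy(), glance() and
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
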