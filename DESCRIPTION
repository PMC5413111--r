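Package: popinfo
Title: Robustness of Neural Population Codes to Downstream Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much stimulus information encoded by a
    noisy neural population survives propagation through a noisy, possibly
    nonlinear, feedforward layer. Provides heterogeneous Von Mises
    tuning-curve populations, constructors for structured noise covariances
    (Poisson-like diagonal base, rank-one perturbations, differential
    correlations, and the alpha-parameterized family that maximizes
    transmitted information), linear Fisher information in the input and
    output layers, a dichotomized-Gaussian spiking channel with Monte Carlo
    information estimation, and seeded experiment pipelines that produce
    tidy tabular results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
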