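Package: gazehmm
Title: Hidden Markov Modelling of Visual-Search Scanpaths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits hidden Markov models with two-dimensional Gaussian
    emissions to fixation sequences recorded during visual search, selects
    the number of hidden states by the Bayesian Information Criterion with
    seeded-restart repair of log-likelihood discontinuities, links hidden
    states to predefined areas of interest (primes and targets), and
    computes the fixation-overlap precision statistic used to compare
    expertise groups. Includes a seeded generator of synthetic search
    scenes and scanpaths with known ground truth, split-plot ANOVA and
    Welch t helpers for group comparison, and kernel density maps of the
    decoded hidden states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
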