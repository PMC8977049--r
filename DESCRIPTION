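Package: trueprev
Title: Bayesian Estimation of True Disease Prevalence with Elicited Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Percentile-based elicitation of Beta and Gamma priors and
    Bayesian estimation of apparent and true disease prevalence from
    diagnostic-test counts, for a single population or multiple
    clusters/studies. Supports imperfect tests through priors on
    sensitivity and specificity, hierarchical beta-binomial pooling across
    clusters, zero-inflation mixtures allowing truly disease-free
    populations, posterior and posterior-predictive freedom-from-disease
    probabilities, and MCMC convergence diagnostics (effective sample
    size, potential scale reduction, autocorrelation, running means,
    chain-density comparisons).
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
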