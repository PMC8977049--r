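# Shared priors and configurations used across test files.

setup_a_model <- function(zero_inflated = FALSE) {
  prev_model("true_single",
             prevalence_prior = elicit_beta(0.5, 0.05, 0.95),
             se_prior = elicit_beta(0.8, 0.75, 0.97),
             sp_prior = elicit_beta(0.9, 0.85, 0.97),
             zero_inflated = zero_inflated,
             w_prior = if (zero_inflated) elicit_beta(0.2, 0.1, 0.95))
}

setup_b_model <- function() {
  prev_model("true_single",
             prevalence_prior = elicit_beta(0.5, 0.08, 0.95),
             se_prior = elicit_beta(0.8, 0.75, 0.97),
             sp_prior = elicit_beta(0.9, 0.85, 0.97))
}

dementia_model <- function() {
  prev_model("true_multi",
             prevalence_prior = beta_prior(0.14, 0.55),
             psi_prior = gamma_prior(1, 0.1),
             se_prior = elicit_beta(0.88, 0.80, 0.90),
             sp_prior = elicit_beta(0.95, 0.85, 0.97))
}

# desk-scale configuration for tests that only need a correct, converged
# posterior rather than publication-tight Monte-Carlo error
quick_cfg <- function(seed = 1, chains = 2) {
  mcmc_config(chains = chains, iterations = 4000, burn_in = 1500,
              thin = 2, seed = seed)
}

# wrap bare per-chain draw matrices as a fit object so the diagnostics
# can be exercised on analytically constructed chains
fake_fit <- function(chains) {
  chains <- lapply(chains, function(m) {
    m <- as.matrix(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
    m
  })
  structure(list(draws = chains, parameters = colnames(chains[[1]]),
                 model = NULL, data = NULL,
                 config = list(seed = 1), clusters = NULL),
            class = "prev_fit")
}
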