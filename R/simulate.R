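#' Simulate single-population test counts
#'
#' Draws `y ~ Binomial(n, pi_t * se + (1 - pi_t) * (1 - sp))`: the
#' generative model for one population tested with an imperfect assay.
#'
#' @param pi_t True prevalence in \[0, 1\].
#' @param se,sp Test sensitivity and specificity in \[0, 1\].
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A list with `data` (a [survey_counts()]) and `truth` (the
#'   generating parameters and seed).
#' @examples
#' simulate_single(0.2, 0.8, 0.9, 500, seed = 1)$data
#' @export
simulate_single <- function(pi_t, se, sp, n, seed = 1) {
  stopifnot(pi_t >= 0, pi_t <= 1, se >= 0, se <= 1, sp >= 0, sp <= 1,
            n > 0)
  set.seed(seed)
  y <- stats::rbinom(1L, n, rogan_gladen(pi_t, se, sp))
  list(data = survey_counts(y, n),
       truth = list(family = "true_single", pi_t = pi_t, se = se, sp = sp,
                    n = n, seed = seed))
}

#' Simulate multi-population test counts
#'
#' Generates a cluster table from the hierarchical model: each cluster is
#' infected with probability `w` (drawing its prevalence from
#' Beta(`mu*psi`, `psi*(1-mu)`)) or disease-free (`pi_t[i] = 0`), and its
#' positives follow `Binomial(n_i, pi_t[i]*se + (1-pi_t[i])*(1-sp))`.
#' `w = 1` disables zero-inflation.
#'
#' @param mu Mean cluster prevalence in (0, 1).
#' @param psi Concentration (> 0); between-cluster variance is
#'   `mu*(1-mu)/(psi+1)`.
#' @param se,sp Shared test accuracy.
#' @param n Vector of per-cluster sample sizes (length k).
#' @param w Infection probability per cluster, default 1.
#' @param seed Integer seed.
#' @return A list with `data` (a `cluster_table` tibble) and `truth`
#'   (including the realized `pi_t` vector and free/infected indicators).
#' @export
simulate_multi <- function(mu, psi, se, sp, n, w = 1, seed = 1) {
  stopifnot(mu > 0, mu < 1, psi > 0, se >= 0, se <= 1, sp >= 0, sp <= 1,
            all(n > 0), w >= 0, w <= 1)
  k <- length(n)
  set.seed(seed)
  z <- stats::rbinom(k, 1L, w)
  pi_t <- ifelse(z == 1L, stats::rbeta(k, mu * psi, psi * (1 - mu)), 0)
  y <- stats::rbinom(k, n, rogan_gladen(pi_t, se, sp))
  data <- validate_cluster_table(
    tibble::tibble(study = as.character(seq_len(k)), positive = y, n = n))
  list(data = data,
       truth = list(family = "true_multi", mu = mu, psi = psi, se = se,
                    sp = sp, w = w, infected = z, pi_t = pi_t, n = n,
                    seed = seed))
}

#' Bundled datasets
#'
#' Returns the packaged example datasets:
#' * `"dementia_9"` — the 9-study European dementia systematic-review
#'   table (DSM-IV diagnoses, patients aged over 65; 18,263 participants,
#'   2,137 positive), as a cluster table.
#' * `"toy_24pct"` — 120 positives of 500 sampled (24% apparent
#'   prevalence).
#' * `"toy_5pct"` — 25 positives of 500 sampled (5% apparent prevalence).
#'
#' @param name One of `"dementia_9"`, `"toy_24pct"`, `"toy_5pct"`.
#' @return A `cluster_table` tibble or a [survey_counts()].
#' @examples
#' load_fixture("toy_24pct")
#' @export
load_fixture <- function(name = c("dementia_9", "toy_24pct", "toy_5pct")) {
  name <- match.arg(name)
  switch(name,
         dementia_9 = read_cluster_table(
           system.file("extdata", "dementia_9.csv", package = "trueprev",
                       mustWork = TRUE)),
         toy_24pct = survey_counts(120, 500),
         toy_5pct = survey_counts(25, 500))
}
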