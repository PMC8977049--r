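#' Survey counts for a single population
#'
#' @param y Number of test-positive subjects (0 <= y <= n).
#' @param n Number of subjects sampled (> 0).
#' @return A one-row tibble with columns `positive` and `n`, classed
#'   `survey_counts`, suitable as the `data` argument of
#'   [fit_prevalence()].
#' @examples
#' survey_counts(120, 500)
#' @export
survey_counts <- function(y, n) {
  stopifnot(is.numeric(y), is.numeric(n), length(y) == 1L, length(n) == 1L)
  if (n <= 0 || n != round(n)) stop("`n` must be a positive integer.",
                                    call. = FALSE)
  if (y < 0 || y > n || y != round(y)) {
    stop("`y` must be an integer with 0 <= y <= n.", call. = FALSE)
  }
  out <- tibble::tibble(positive = as.integer(y), n = as.integer(n))
  class(out) <- c("survey_counts", class(out))
  out
}

# Coerce `data` to a validated tibble with integer columns positive/n.
# Accepts survey_counts, a cluster table, or any data frame carrying
# columns named positive (or y) and n.
as_count_data <- function(data) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with columns `positive` and `n` ",
         "(see survey_counts() and read_cluster_table()).", call. = FALSE)
  }
  nms <- tolower(trimws(names(data)))
  pos_col <- which(nms == "positive")
  if (length(pos_col) == 0L) pos_col <- which(nms == "y")
  n_col <- which(nms == "n")
  if (length(pos_col) != 1L || length(n_col) != 1L) {
    stop("`data` must have exactly one `positive` (or `y`) column and one ",
         "`n` column.", call. = FALSE)
  }
  y <- data[[pos_col]]
  n <- data[[n_col]]
  if (nrow(data) < 1L) stop("`data` must have at least one row.",
                            call. = FALSE)
  bad <- which(!is.finite(y) | !is.finite(n) | y != round(y) |
                 n != round(n) | n <= 0 | y < 0 | y > n)
  if (length(bad) > 0L) {
    stop(sprintf("Invalid counts in `data` row(s) %s: need integers with 0 <= positive <= n.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  labels <- if ("study" %in% nms) {
    as.character(data[[which(nms == "study")[1]]])
  } else {
    as.character(seq_len(nrow(data)))
  }
  tibble::tibble(study = labels, positive = as.integer(y), n = as.integer(n))
}

#' Specify a prevalence model
#'
#' Assembles the model family, priors and zero-inflation option consumed by
#' [fit_prevalence()].
#'
#' Families:
#' * `"apparent_single"` — binomial model for the apparent prevalence
#'   `pi_a` (probability of a positive test) with a conjugate Beta prior.
#' * `"true_single"` — binomial model for the true prevalence `pi_t` of one
#'   population tested with an imperfect assay: the success probability is
#'   `pi_t * Se + (1 - pi_t) * (1 - Sp)`, with Beta (or fixed) priors on
#'   sensitivity `Se` and specificity `Sp`.
#' * `"true_multi"` — hierarchical beta-binomial model for k clusters:
#'   cluster prevalences `pi_t[i] | mu, psi ~ Beta(mu*psi, psi*(1-mu))`
#'   share `Se`/`Sp`; `mu` carries a Beta prior and `psi` a Gamma prior.
#'
#' With `zero_inflated = TRUE` each population is, with probability
#' `1 - w`, entirely free of disease (`pi = 0`); `w` carries a Beta prior.
#' The mixture is marginalized analytically in the sampler.
#'
#' @param family One of `"apparent_single"`, `"true_single"`,
#'   `"true_multi"`.
#' @param prevalence_prior A [beta_prior()] for single-population families;
#'   for `"true_multi"` a list with components `mu` ([beta_prior()]) and
#'   `psi` ([gamma_prior()]), e.g. from [elicit_hierarchical()]. For
#'   `"true_multi"` a bare [beta_prior()] is also accepted as the `mu`
#'   prior, with `psi_prior` supplying the Gamma part.
#' @param se_prior,sp_prior [beta_prior()] or [point_mass()]; required for
#'   (and only for) the true-prevalence families.
#' @param psi_prior Optional [gamma_prior()] for `psi`; default
#'   Gamma(1, 0.1), a weakly informative choice spanning strong to weak
#'   between-cluster heterogeneity.
#' @param zero_inflated Allow a point mass at zero prevalence?
#' @param w_prior [beta_prior()] for the infection probability `w`;
#'   required iff `zero_inflated`.
#' @return An object of class `prev_model`.
#' @examples
#' prev_model("true_single",
#'   prevalence_prior = elicit_beta(0.5, 0.05, 0.95),
#'   se_prior = elicit_beta(0.8, 0.75, 0.97),
#'   sp_prior = elicit_beta(0.9, 0.85, 0.97))
#' @export
prev_model <- function(family = c("apparent_single", "true_single",
                                  "true_multi"),
                       prevalence_prior,
                       se_prior = NULL, sp_prior = NULL,
                       psi_prior = NULL,
                       zero_inflated = FALSE, w_prior = NULL) {
  family <- match.arg(family)
  is_true <- family != "apparent_single"

  if (family == "true_multi") {
    if (is.list(prevalence_prior) && !inherits(prevalence_prior, "beta_prior") &&
        all(c("mu", "psi") %in% names(prevalence_prior))) {
      mu_prior <- prevalence_prior$mu
      psi_prior <- prevalence_prior$psi
    } else {
      mu_prior <- prevalence_prior
      if (is.null(psi_prior)) psi_prior <- gamma_prior(1, 0.1)
    }
    stopifnot(inherits(mu_prior, "beta_prior"),
              inherits(psi_prior, "gamma_prior"))
    prevalence_prior <- list(mu = mu_prior, psi = psi_prior)
  } else {
    if (!inherits(prevalence_prior, "beta_prior")) {
      stop("`prevalence_prior` must be a beta_prior for single-population ",
           "families.", call. = FALSE)
    }
    if (!is.null(psi_prior)) {
      stop("`psi_prior` only applies to family 'true_multi'.", call. = FALSE)
    }
  }

  if (is_true) {
    if (is.null(se_prior) || is.null(sp_prior)) {
      stop("True-prevalence families require `se_prior` and `sp_prior`.",
           call. = FALSE)
    }
    ok <- function(p) inherits(p, "beta_prior") || inherits(p, "point_mass")
    if (!ok(se_prior) || !ok(sp_prior)) {
      stop("`se_prior` and `sp_prior` must be beta_prior or point_mass.",
           call. = FALSE)
    }
    # identifiability: the apparent-true map is increasing only when
    # Se + Sp > 1; warn when the priors put appreciable mass elsewhere
    pm <- function(p) if (inherits(p, "point_mass")) p$value else
      p$alpha / (p$alpha + p$beta)
    if (pm(se_prior) + pm(sp_prior) <= 1) {
      warning("Prior means give Se + Sp <= 1: true prevalence is only ",
              "weakly identified and the posterior may label-switch.",
              call. = FALSE)
    }
  } else if (!is.null(se_prior) || !is.null(sp_prior)) {
    stop("`se_prior`/`sp_prior` do not apply to the apparent-prevalence ",
         "family.", call. = FALSE)
  }

  if (zero_inflated) {
    if (!inherits(w_prior, "beta_prior")) {
      stop("`zero_inflated = TRUE` requires a beta_prior `w_prior`.",
           call. = FALSE)
    }
  } else if (!is.null(w_prior)) {
    stop("`w_prior` given but `zero_inflated` is FALSE.", call. = FALSE)
  }

  structure(list(family = family, prevalence_prior = prevalence_prior,
                 se_prior = se_prior, sp_prior = sp_prior,
                 zero_inflated = zero_inflated, w_prior = w_prior),
            class = "prev_model")
}

#' @export
print.prev_model <- function(x, ...) {
  cat("<prev_model>", x$family,
      if (x$zero_inflated) "(zero-inflated)" else "", "\n")
  invisible(x)
}

#' Apparent-to-true prevalence map (Rogan-Gladen relation)
#'
#' The probability of a positive test given true prevalence `pi_t` and test
#' accuracy: `pi_a = pi_t * se + (1 - pi_t) * (1 - sp)`. Affine in `pi_t`,
#' increasing when `se + sp > 1`. Vectorized.
#'
#' @param pi_t,se,sp Probabilities in \[0, 1\].
#' @return Apparent prevalence in \[0, 1\].
#' @examples
#' rogan_gladen(0.2015, 0.8, 0.9)  # 0.24105
#' @export
rogan_gladen <- function(pi_t, se, sp) {
  stopifnot(all(pi_t >= 0 & pi_t <= 1), all(se >= 0 & se <= 1),
            all(sp >= 0 & sp <= 1))
  pmin(1, pmax(0, pi_t * se + (1 - pi_t) * (1 - sp)))
}

#' Conjugate posterior for apparent prevalence
#'
#' With `y` positives of `n` and a Beta(alpha, beta) prior the posterior of
#' the apparent prevalence is Beta(alpha + y, beta + n - y), exactly.
#'
#' @param data A [survey_counts()] (or one-row data frame with
#'   `positive`/`n`).
#' @param prior A [beta_prior()].
#' @return A [beta_prior()] holding the posterior hyperparameters.
#' @examples
#' apparent_posterior(survey_counts(120, 500), beta_prior(1, 1))
#' @export
apparent_posterior <- function(data, prior) {
  d <- as_count_data(data)
  if (nrow(d) != 1L) stop("`data` must describe a single population.",
                          call. = FALSE)
  stopifnot(inherits(prior, "beta_prior"))
  beta_prior(prior$alpha + d$positive, prior$beta + d$n - d$positive)
}

#' Log-likelihood of single-population counts under the true-prevalence model
#'
#' Binomial log-pmf of the observed positives with success probability
#' [rogan_gladen()]`(pi_t, se, sp)`. Vectorized over the parameters.
#'
#' @param pi_t,se,sp Parameter values in \[0, 1\].
#' @param data A [survey_counts()].
#' @return Log-density (`-Inf` where the data are impossible).
#' @export
loglik_true_single <- function(pi_t, se, sp, data) {
  d <- as_count_data(data)
  if (nrow(d) != 1L) stop("`data` must describe a single population.",
                          call. = FALSE)
  stats::dbinom(d$positive, d$n, rogan_gladen(pi_t, se, sp), log = TRUE)
}

#' Log-likelihood of a cluster table under the shared-test model
#'
#' Sum of per-cluster binomial log-pmfs with cluster-specific true
#' prevalences and sensitivity/specificity shared across clusters.
#'
#' @param pi_t Vector of cluster prevalences, one per data row.
#' @param se,sp Shared test accuracy.
#' @param data A cluster table (see [read_cluster_table()]).
#' @return Scalar log-density.
#' @export
loglik_true_multi <- function(pi_t, se, sp, data) {
  d <- as_count_data(data)
  if (length(pi_t) != nrow(d)) {
    stop("`pi_t` must have one entry per cluster.", call. = FALSE)
  }
  sum(stats::dbinom(d$positive, d$n, rogan_gladen(pi_t, se, sp), log = TRUE))
}

#' Log-density of cluster prevalences under the hierarchical prior
#'
#' Exchangeable cluster prevalences follow Beta(mu*psi, psi*(1-mu)): mean
#' `mu`, variance `mu*(1-mu)/(psi+1)`, so larger `psi` means less
#' between-cluster heterogeneity.
#'
#' @param pi_t Vector of cluster prevalences in (0, 1).
#' @param mu Mean prevalence in (0, 1).
#' @param psi Concentration, positive.
#' @return Scalar log-density (`-Inf` at boundary values).
#' @export
log_hier_prior <- function(pi_t, mu, psi) {
  stopifnot(mu > 0, mu < 1, psi > 0)
  sum(stats::dbeta(pi_t, mu * psi, psi * (1 - mu), log = TRUE))
}

#' Marginalized zero-inflation mixture log-likelihood
#'
#' With probability `w` a population is infected and its counts follow the
#' family likelihood at prevalence `pi`; with probability `1 - w` it is
#' disease-free (`pi = 0`), in which case positives arise only as false
#' positives (success probability `1 - sp`; exactly 0 for the apparent
#' family). The latent free/infected indicator is summed out; for a cluster
#' table the mixture applies independently per cluster.
#'
#' @param pi Prevalence (scalar, or one value per cluster for
#'   `"true_multi"`).
#' @param w Infection probability in (0, 1).
#' @param data [survey_counts()] or a cluster table.
#' @param se,sp Test accuracy (ignored for the apparent family).
#' @param family Model family, as in [prev_model()].
#' @return Scalar log-density.
#' @export
mixture_loglik <- function(pi, w, data,
                           se = NULL, sp = NULL,
                           family = c("true_single", "true_multi",
                                      "apparent_single")) {
  family <- match.arg(family)
  stopifnot(w > 0, w < 1)
  d <- as_count_data(data)
  if (family != "true_multi" && nrow(d) != 1L) {
    stop("`data` must describe a single population for this family.",
         call. = FALSE)
  }
  if (family == "true_multi" && length(pi) != nrow(d)) {
    stop("`pi` must have one entry per cluster.", call. = FALSE)
  }
  if (family == "apparent_single") {
    l1 <- stats::dbinom(d$positive, d$n, pi, log = TRUE)
    l0 <- ifelse(d$positive == 0, 0, -Inf)
  } else {
    l1 <- stats::dbinom(d$positive, d$n, rogan_gladen(pi, se, sp),
                        log = TRUE)
    l0 <- stats::dbinom(d$positive, d$n, 1 - sp, log = TRUE)
  }
  sum(log_mix_pair(log(w) + l1, log(1 - w) + l0))
}

# stable log( exp(a) + exp(b) ), elementwise
log_mix_pair <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Apparent prevalence point estimates with Wald intervals
#'
#' `y/n` with normal-approximation confidence bounds
#' `y/n -/+ z * sqrt(p(1-p)/n)`, truncated to \[0, 1\]. Row-wise over a
#' cluster table, so piping a study table straight in reproduces the usual
#' per-study apparent-prevalence columns.
#'
#' @param data [survey_counts()] or a cluster table.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `study`, `positive`, `n`, `estimate`,
#'   `lower`, `upper`.
#' @examples
#' wald_interval(survey_counts(60, 961))
#' @export
wald_interval <- function(data, level = 0.95) {
  d <- as_count_data(data)
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- d$positive / d$n
  half <- z * sqrt(p * (1 - p) / d$n)
  tibble::tibble(study = d$study, positive = d$positive, n = d$n,
                 estimate = p,
                 lower = pmax(0, p - half),
                 upper = pmin(1, p + half))
}
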