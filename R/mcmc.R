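#' MCMC configuration
#'
#' Settings for the adaptive random-walk Metropolis-within-Gibbs sampler.
#' Defaults (4 chains of 30,000 iterations, 10,000 burn-in, thinning 5)
#' retain 4 x 4,000 draws, enough that posterior means of the bundled
#' examples are stable to about +/-0.005 across seeds.
#'
#' @param chains Number of chains (>= 2, so convergence diagnostics are
#'   defined).
#' @param iterations Iterations per chain, including burn-in.
#' @param burn_in Iterations discarded per chain; proposal step sizes adapt
#'   only during burn-in and are frozen afterwards, preserving detailed
#'   balance of the retained draws.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   draws.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 30000, burn_in = 10000,
                        thin = 5, seed = 1) {
  stopifnot(chains >= 2, iterations > 0, burn_in >= 0, thin >= 1)
  if (burn_in >= iterations) {
    stop("`burn_in` must be smaller than `iterations`.", call. = FALSE)
  }
  if ((iterations - burn_in) < thin) {
    stop("No draws would be retained; reduce `thin` or `burn_in`.",
         call. = FALSE)
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

clamp01 <- function(p, eps = 1e-4) pmin(1 - eps, pmax(eps, p))

draw_from <- function(prior, n) {
  if (inherits(prior, "beta_prior")) {
    clamp01(stats::rbeta(n, prior$alpha, prior$beta))
  } else if (inherits(prior, "gamma_prior")) {
    pmax(1e-3, stats::rgamma(n, prior$shape, prior$rate))
  } else {
    rep(prior$value, n)
  }
}

#' Fit a prevalence model by MCMC
#'
#' Draws posterior samples for any [prev_model()] with an adaptive
#' random-walk Metropolis-within-Gibbs sampler. Probability-scale
#' parameters are updated on the logit scale and `psi` on the log scale;
#' each parameter block has a per-chain proposal step size tuned towards a
#' 44% acceptance rate during burn-in and frozen afterwards. Chains start
#' from independent draws out of the priors, so they are overdispersed
#' relative to the posterior. All chains are advanced together in
#' vectorized updates.
#'
#' For zero-inflated models the disease-free/infected indicator is
#' marginalized out of the sampler state and re-imputed per retained draw
#' afterwards; the mixture prevalence (`pi` when infected, exactly 0 when
#' free) is stored as the additional parameter `pi_star` (per cluster for
#' the multi-population family).
#'
#' @param data A [survey_counts()] for single-population families or a
#'   cluster table (see [read_cluster_table()]) for `"true_multi"`.
#' @param model A [prev_model()].
#' @param config An [mcmc_config()].
#' @return An object of class `prev_fit`: retained draws per chain plus the
#'   model, data and configuration that produced them.
#' @examples
#' fit <- survey_counts(120, 500) |>
#'   fit_prevalence(
#'     prev_model("apparent_single", prevalence_prior = beta_prior(1, 1)),
#'     mcmc_config(chains = 2, iterations = 2000, burn_in = 500, seed = 1))
#' posterior_summary(fit)
#' @export
fit_prevalence <- function(data, model, config = mcmc_config()) {
  stopifnot(inherits(model, "prev_model"), inherits(config, "mcmc_config"))
  d <- as_count_data(data)
  if (model$family == "true_multi") {
    if (nrow(d) < 1L) stop("Cluster table is empty.", call. = FALSE)
  } else if (nrow(d) != 1L) {
    stop(sprintf("Family '%s' needs single-population data (1 row), got %d.",
                 model$family, nrow(d)), call. = FALSE)
  }

  C <- config$chains
  k <- nrow(d)
  hier <- model$family == "true_multi"
  is_true <- model$family != "apparent_single"
  zi <- model$zero_inflated

  se_sampled <- is_true && inherits(model$se_prior, "beta_prior")
  sp_sampled <- is_true && inherits(model$sp_prior, "beta_prior")

  Ym <- matrix(d$positive, C, k, byrow = TRUE)
  Nm <- matrix(d$n, C, k, byrow = TRUE)

  set.seed(config$seed)

  # ---- initial state, overdispersed draws from the priors -------------
  if (hier) {
    mu <- clamp01(draw_from(model$prevalence_prior$mu, C), 1e-3)
    psi <- draw_from(model$prevalence_prior$psi, C)
    P <- matrix(clamp01(stats::rbeta(C * k, rep(mu * psi, k),
                                     rep(psi * (1 - mu), k))), C, k)
  } else {
    mu <- psi <- NULL
    P <- matrix(clamp01(draw_from(model$prevalence_prior, C)), C, 1)
  }
  se <- if (is_true) draw_from(model$se_prior, C) else NULL
  sp <- if (is_true) draw_from(model$sp_prior, C) else NULL
  w <- if (zi) clamp01(draw_from(model$w_prior, C), 1e-3) else NULL

  succ <- function(P, se, sp) {
    if (is_true) P * se + (1 - P) * (1 - sp) else P
  }
  bin_ll <- function(PM) stats::dbinom(Ym, Nm, PM, log = TRUE)

  L1 <- bin_ll(succ(P, se, sp))
  L0 <- if (zi) {
    if (is_true) bin_ll(matrix(1 - sp, C, k)) else
      matrix(ifelse(Ym == 0, 0, -Inf), C, k)
  } else NULL
  mix_ll <- function(L1, L0, w) log_mix_pair(log(w) + L1, log(1 - w) + L0)
  Ldat <- if (zi) mix_ll(L1, L0, w) else L1

  # per-entry log-densities of the prevalence prior (without jacobian)
  prior_pi <- function(P, mu, psi) {
    if (hier) stats::dbeta(P, mu * psi, psi * (1 - mu), log = TRUE)
    else stats::dbeta(P, model$prevalence_prior$alpha,
                      model$prevalence_prior$beta, log = TRUE)
  }
  PrP <- prior_pi(P, mu, psi)

  ljac <- function(p) log(p) + log1p(-p)   # |d p / d logit(p)|

  # ---- adaptive step sizes -------------------------------------------
  ls_pi <- matrix(log(0.5), C, k)
  ls_se <- rep(log(0.2), C); ls_sp <- rep(log(0.2), C)
  ls_mu <- rep(log(0.5), C); ls_psi <- rep(log(0.5), C)
  ls_w <- rep(log(0.5), C)
  target_acc <- 0.44

  n_ret <- (config$iterations - config$burn_in) %/% config$thin
  par_names <- c(
    if (hier) paste0("pi_t[", d$study, "]")
    else if (is_true) "pi_t" else "pi_a",
    if (is_true) c("se", "sp"),
    if (hier) c("mu", "psi"),
    if (zi) "w")
  n_par <- length(par_names)
  A <- array(NA_real_, c(n_ret, n_par, C),
             dimnames = list(NULL, par_names, NULL))
  r <- 0L

  for (it in seq_len(config$iterations)) {
    adapting <- it <= config$burn_in
    gam <- if (adapting) it^(-0.6) else 0

    # -- prevalence block: conditionally independent components ---------
    Z <- logit(P)
    Zn <- Z + exp(ls_pi) * matrix(stats::rnorm(C * k), C, k)
    Pn <- inv_logit(Zn)
    L1n <- bin_ll(succ(Pn, se, sp))
    Ldn <- if (zi) mix_ll(L1n, L0, w) else L1n
    PrPn <- prior_pi(Pn, mu, psi)
    delta <- (Ldn - Ldat) + (PrPn - PrP) + (ljac(Pn) - ljac(P))
    delta[is.nan(delta)] <- -Inf
    acc <- log(stats::runif(C * k)) < delta
    P[acc] <- Pn[acc]; L1[acc] <- L1n[acc]; Ldat[acc] <- Ldn[acc]
    PrP[acc] <- PrPn[acc]
    if (adapting) ls_pi <- ls_pi + gam * (pmin(1, exp(delta)) - target_acc)

    # -- sensitivity ----------------------------------------------------
    if (se_sampled) {
      zn <- logit(se) + exp(ls_se) * stats::rnorm(C)
      sen <- inv_logit(zn)
      L1n <- bin_ll(succ(P, sen, sp))
      Ldn <- if (zi) mix_ll(L1n, L0, w) else L1n
      delta <- rowSums(Ldn - Ldat) +
        stats::dbeta(sen, model$se_prior$alpha, model$se_prior$beta,
                     log = TRUE) -
        stats::dbeta(se, model$se_prior$alpha, model$se_prior$beta,
                     log = TRUE) +
        ljac(sen) - ljac(se)
      delta[is.nan(delta)] <- -Inf
      acc <- log(stats::runif(C)) < delta
      se[acc] <- sen[acc]
      L1[acc, ] <- L1n[acc, ]; Ldat[acc, ] <- Ldn[acc, ]
      if (adapting) ls_se <- ls_se + gam * (pmin(1, exp(delta)) - target_acc)
    }

    # -- specificity (enters both mixture components) -------------------
    if (sp_sampled) {
      zn <- logit(sp) + exp(ls_sp) * stats::rnorm(C)
      spn <- inv_logit(zn)
      L1n <- bin_ll(succ(P, se, spn))
      L0n <- if (zi) bin_ll(matrix(1 - spn, C, k)) else NULL
      Ldn <- if (zi) mix_ll(L1n, L0n, w) else L1n
      delta <- rowSums(Ldn - Ldat) +
        stats::dbeta(spn, model$sp_prior$alpha, model$sp_prior$beta,
                     log = TRUE) -
        stats::dbeta(sp, model$sp_prior$alpha, model$sp_prior$beta,
                     log = TRUE) +
        ljac(spn) - ljac(sp)
      delta[is.nan(delta)] <- -Inf
      acc <- log(stats::runif(C)) < delta
      sp[acc] <- spn[acc]
      L1[acc, ] <- L1n[acc, ]; Ldat[acc, ] <- Ldn[acc, ]
      if (zi) L0[acc, ] <- L0n[acc, ]
      if (adapting) ls_sp <- ls_sp + gam * (pmin(1, exp(delta)) - target_acc)
    }

    if (hier) {
      pr <- model$prevalence_prior
      # -- mean prevalence mu ------------------------------------------
      zn <- logit(mu) + exp(ls_mu) * stats::rnorm(C)
      mun <- inv_logit(zn)
      PrPn <- prior_pi(P, mun, psi)
      delta <- rowSums(PrPn - PrP) +
        stats::dbeta(mun, pr$mu$alpha, pr$mu$beta, log = TRUE) -
        stats::dbeta(mu, pr$mu$alpha, pr$mu$beta, log = TRUE) +
        ljac(mun) - ljac(mu)
      delta[is.nan(delta)] <- -Inf
      acc <- log(stats::runif(C)) < delta
      mu[acc] <- mun[acc]; PrP[acc, ] <- PrPn[acc, ]
      if (adapting) ls_mu <- ls_mu + gam * (pmin(1, exp(delta)) - target_acc)

      # -- concentration psi (log scale) -------------------------------
      zn <- log(psi) + exp(ls_psi) * stats::rnorm(C)
      psin <- exp(zn)
      PrPn <- prior_pi(P, mu, psin)
      delta <- rowSums(PrPn - PrP) +
        stats::dgamma(psin, pr$psi$shape, pr$psi$rate, log = TRUE) -
        stats::dgamma(psi, pr$psi$shape, pr$psi$rate, log = TRUE) +
        log(psin) - log(psi)
      delta[is.nan(delta)] <- -Inf
      acc <- log(stats::runif(C)) < delta
      psi[acc] <- psin[acc]; PrP[acc, ] <- PrPn[acc, ]
      if (adapting) ls_psi <- ls_psi + gam * (pmin(1, exp(delta)) - target_acc)
    }

    # -- zero-inflation weight w ---------------------------------------
    if (zi) {
      zn <- logit(w) + exp(ls_w) * stats::rnorm(C)
      wn <- inv_logit(zn)
      Ldn <- mix_ll(L1, L0, wn)
      delta <- rowSums(Ldn - Ldat) +
        stats::dbeta(wn, model$w_prior$alpha, model$w_prior$beta,
                     log = TRUE) -
        stats::dbeta(w, model$w_prior$alpha, model$w_prior$beta,
                     log = TRUE) +
        ljac(wn) - ljac(w)
      delta[is.nan(delta)] <- -Inf
      acc <- log(stats::runif(C)) < delta
      w[acc] <- wn[acc]; Ldat[acc, ] <- Ldn[acc, ]
      if (adapting) ls_w <- ls_w + gam * (pmin(1, exp(delta)) - target_acc)
    }

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      r <- r + 1L
      S <- cbind(P,
                 if (is_true) if (se_sampled) se else rep(model$se_prior$value, C),
                 if (is_true) if (sp_sampled) sp else rep(model$sp_prior$value, C),
                 if (hier) mu, if (hier) psi,
                 if (zi) w)
      A[r, , ] <- t(S)
    }
  }

  draws <- lapply(seq_len(C), function(ch) {
    m <- A[, , ch, drop = FALSE]
    dim(m) <- c(n_ret, n_par)
    colnames(m) <- par_names
    m
  })

  # re-impute the latent free/infected indicator per retained draw and
  # store the mixture prevalence pi_star = z * pi (0 when disease-free)
  if (zi) {
    star_names <- if (hier) paste0("pi_star[", d$study, "]") else "pi_star"
    draws <- lapply(draws, function(m) {
      pim <- m[, seq_len(k), drop = FALSE]
      wv <- m[, "w"]
      if (is_true) {
        sev <- m[, "se"]; spv <- m[, "sp"]
        l1 <- stats::dbinom(matrix(d$positive, n_ret, k, byrow = TRUE),
                            matrix(d$n, n_ret, k, byrow = TRUE),
                            pim * sev + (1 - pim) * (1 - spv), log = TRUE)
        l0 <- stats::dbinom(matrix(d$positive, n_ret, k, byrow = TRUE),
                            matrix(d$n, n_ret, k, byrow = TRUE),
                            matrix(1 - spv, n_ret, k), log = TRUE)
      } else {
        l1 <- stats::dbinom(matrix(d$positive, n_ret, k, byrow = TRUE),
                            matrix(d$n, n_ret, k, byrow = TRUE),
                            pim, log = TRUE)
        l0 <- matrix(ifelse(rep(d$positive, each = n_ret) == 0, 0, -Inf),
                     n_ret, k)
      }
      p1 <- 1 / (1 + exp(log1p(-wv) + l0 - log(wv) - l1))
      p1[l0 == -Inf] <- 1
      z <- matrix(stats::rbinom(n_ret * k, 1L, p1), n_ret, k)
      star <- z * pim
      colnames(star) <- star_names
      cbind(m, star)
    })
  }

  structure(list(draws = draws, parameters = colnames(draws[[1]]),
                 model = model, data = d, config = config,
                 clusters = if (hier) d$study else NULL),
            class = "prev_fit")
}

#' @export
print.prev_fit <- function(x, ...) {
  cat(sprintf("<prev_fit> %s%s: %d chains x %d retained draws\n",
              x$model$family,
              if (x$model$zero_inflated) " (zero-inflated)" else "",
              length(x$draws), nrow(x$draws[[1]])))
  print(posterior_summary(x))
  invisible(x)
}

# nret x nchains matrix for one parameter
param_matrix <- function(fit, parameter) {
  stopifnot(inherits(fit, "prev_fit"))
  if (!parameter %in% fit$parameters) {
    stop(sprintf("Unknown parameter '%s'. Available: %s.", parameter,
                 paste(fit$parameters, collapse = ", ")), call. = FALSE)
  }
  vapply(fit$draws, function(m) m[, parameter], numeric(nrow(fit$draws[[1]])))
}

pooled_draws <- function(fit, parameter) as.vector(param_matrix(fit, parameter))

#' Extract posterior draws as a tidy tibble
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameters Optional character vector restricting the parameters.
#' @return A long tibble with columns `.chain`, `.iteration` (index among
#'   retained draws), `parameter`, `value`.
#' @export
posterior_draws <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "prev_fit"))
  parameters <- parameters %||% fit$parameters
  purrr::map_dfr(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]][, parameters, drop = FALSE]
    tibble::tibble(.chain = ch,
                   .iteration = rep(seq_len(nrow(m)), length(parameters)),
                   parameter = rep(parameters, each = nrow(m)),
                   value = as.vector(m))
  })
}

# median-unbiased empirical quantiles (type 8), the package-wide convention
post_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 8, names = FALSE)
}

#' Posterior summaries
#'
#' Pooled-chain mean, median and central credible-interval quantiles per
#' parameter. Quantiles use the median-unbiased empirical convention
#' (type 8).
#'
#' @param fit A [fit_prevalence()] result.
#' @param level Credible level (default 0.95, i.e. the 2.5% and 97.5%
#'   quantiles).
#' @param parameters Optional restriction.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `median`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(fit, level = 0.95, parameters = NULL) {
  stopifnot(inherits(fit, "prev_fit"), level > 0, level < 1)
  parameters <- parameters %||% fit$parameters
  a <- (1 - level) / 2
  purrr::map_dfr(parameters, function(p) {
    x <- pooled_draws(fit, p)
    q <- post_quantile(x, c(a, 0.5, 1 - a))
    tibble::tibble(parameter = p, mean = mean(x), sd = stats::sd(x),
                   median = q[2], lower = q[1], upper = q[3])
  })
}

#' Posterior probability of exceeding a threshold
#'
#' Fraction of pooled posterior draws strictly above `threshold`, e.g. the
#' probability that the mean regional prevalence exceeds 5%.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @param threshold Numeric threshold.
#' @return A probability.
#' @export
prob_exceeds <- function(fit, parameter, threshold) {
  mean(pooled_draws(fit, parameter) > threshold)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prevalence fit
#'
#' One row per parameter with the posterior mean (`estimate`), posterior
#' standard deviation (`std.error`), median and credible bounds.
#'
#' @param x A [fit_prevalence()] result.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble with broom-style columns.
#' @export
tidy.prev_fit <- function(x, level = 0.95, ...) {
  s <- posterior_summary(x, level = level)
  tibble::tibble(term = s$parameter, estimate = s$mean,
                 std.error = s$sd, median = s$median,
                 conf.low = s$lower, conf.high = s$upper)
}

#' Glance at a prevalence fit
#'
#' @param x A [fit_prevalence()] result.
#' @param ... Unused.
#' @return A one-row tibble: family, zero-inflation flag, chain/draw
#'   counts, worst-case shrink factor and smallest effective sample size
#'   over parameters.
#' @export
glance.prev_fit <- function(x, ...) {
  dg <- mcmc_diagnostics(x)
  tibble::tibble(family = x$model$family,
                 zero_inflated = x$model$zero_inflated,
                 chains = length(x$draws),
                 draws = nrow(x$draws[[1]]) * length(x$draws),
                 max_shrink = max(dg$shrink_factor, na.rm = TRUE),
                 min_ess = min(dg$ess, na.rm = TRUE))
}

#' Freedom-from-disease summaries for a hierarchical fit
#'
#' For a multi-population fit, computes the quantities used to judge
#' disease freedom at a prevalence level `threshold`:
#' (a) per-cluster posterior summaries of the cluster prevalences,
#' (b) the fitted prevalence-distribution parameters (`mu*psi`,
#' `psi*(1-mu)`) per draw, (c) the posterior summary of the mean
#' prevalence `mu`, (d) the posterior probability that every sampled
#' cluster is below `threshold` (using the mixture prevalence when
#' zero-inflated), and (e) the posterior-predictive probability that a new,
#' unsampled cluster is below `threshold` — one predictive prevalence is
#' drawn from Beta(`mu*psi`, `psi*(1-mu)`) per retained draw, preceded by a
#' free/infected coin flip with probability `1 - w` when zero-inflated.
#'
#' @param fit A `"true_multi"` [fit_prevalence()] result.
#' @param threshold Prevalence level `c` defining freedom (default 0.02).
#' @param seed Seed for the posterior-predictive draws (defaults to the
#'   fit's own seed, so the result is reproducible from the fit alone).
#' @return A list of class `freedom_summary` with elements
#'   `cluster_summary`, `fitted_beta`, `mu_summary`, `p_region_free`,
#'   `p_predictive_free` and, when zero-inflated, `p_region_free_mixture`.
#' @export
freedom_summaries <- function(fit, threshold = 0.02, seed = NULL) {
  stopifnot(inherits(fit, "prev_fit"))
  if (fit$model$family != "true_multi") {
    stop("Freedom summaries require a hierarchical ('true_multi') fit.",
         call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1)
  zi <- fit$model$zero_inflated
  pi_pars <- paste0("pi_t[", fit$clusters, "]")
  Pi <- do.call(rbind, lapply(fit$draws, function(m) {
    m[, pi_pars, drop = FALSE]
  }))
  mu <- pooled_draws(fit, "mu")
  psi <- pooled_draws(fit, "psi")
  w <- if (zi) pooled_draws(fit, "w") else NULL

  region_pi <- if (zi) {
    do.call(rbind, lapply(fit$draws, function(m) {
      m[, paste0("pi_star[", fit$clusters, "]"), drop = FALSE]
    }))
  } else Pi

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed %||% fit$config$seed)
  pred_pi <- stats::rbeta(length(mu), mu * psi, psi * (1 - mu))
  pred_z <- if (zi) stats::rbinom(length(mu), 1L, w) else rep(1L, length(mu))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  out <- list(
    threshold = threshold,
    cluster_summary = posterior_summary(fit, parameters = pi_pars),
    fitted_beta = tibble::tibble(alpha = mu * psi, beta = psi * (1 - mu)),
    mu_summary = posterior_summary(fit, parameters = "mu"),
    p_region_free = mean(rowSums(region_pi < threshold) == ncol(region_pi)),
    p_predictive_free = mean(pred_z == 0L | pred_pi < threshold))
  if (zi) {
    out$p_region_free_mixture <- mean(rowSums(region_pi == 0) ==
                                        ncol(region_pi))
  }
  structure(out, class = "freedom_summary")
}

#' @export
print.freedom_summary <- function(x, ...) {
  cat(sprintf("Freedom-from-disease summaries at level c = %g\n",
              x$threshold))
  cat(sprintf("  P(all sampled clusters < c | data) = %.4f\n",
              x$p_region_free))
  cat(sprintf("  P(new cluster < c | data)          = %.4f\n",
              x$p_predictive_free))
  if (!is.null(x$p_region_free_mixture)) {
    cat(sprintf("  P(all sampled clusters disease-free) = %.4f\n",
                x$p_region_free_mixture))
  }
  cat("Mean prevalence (mu):\n")
  print(x$mu_summary)
  invisible(x)
}
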