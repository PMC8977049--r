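#' Beta prior
#'
#' Container for the two hyperparameters of a Beta distribution, used as the
#' prior for any probability-scale parameter of the prevalence models: the
#' prevalence itself (apparent or true), test sensitivity and specificity,
#' the mean prevalence `mu` of a hierarchical fit, and the infection
#' probability `w` of a zero-inflation mixture.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_prior`.
#' @examples
#' beta_prior(1, 1)            # uniform on (0, 1)
#' summarize_prior(beta_prior(0.14, 0.55))
#' @export
beta_prior <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1L,
            length(beta) == 1L)
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("`alpha` and `beta` must be finite and strictly positive.",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' Gamma prior
#'
#' Container for the shape and rate of a Gamma distribution, used as the
#' prior for the concentration parameter `psi` of the hierarchical
#' beta-binomial model. Large `psi` means low between-cluster heterogeneity:
#' cluster prevalences Beta(mu*psi, psi*(1-mu)) have variance
#' mu(1-mu)/(psi+1).
#'
#' @param shape,rate Positive parameters (rate, not scale).
#' @return An object of class `gamma_prior`.
#' @export
gamma_prior <- function(shape, rate) {
  stopifnot(is.numeric(shape), is.numeric(rate), length(shape) == 1L,
            length(rate) == 1L)
  if (!is.finite(shape) || !is.finite(rate) || shape <= 0 || rate <= 0) {
    stop("`shape` and `rate` must be finite and strictly positive.",
         call. = FALSE)
  }
  structure(list(shape = shape, rate = rate), class = "gamma_prior")
}

#' Point-mass (fixed-value) prior
#'
#' Degenerate prior fixing a parameter at a known value, e.g. sensitivity
#' and specificity treated as known constants rather than estimated.
#'
#' @param value A probability in \[0, 1\].
#' @return An object of class `point_mass`.
#' @export
point_mass <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value) || value < 0 || value > 1) {
    stop("`value` must lie in [0, 1].", call. = FALSE)
  }
  structure(list(value = value), class = "point_mass")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("<beta_prior> Beta(%.2f, %.2f)\n", x$alpha, x$beta))
  invisible(x)
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("<gamma_prior> Gamma(shape = %.2f, rate = %.2f)\n",
              x$shape, x$rate))
  invisible(x)
}

#' @export
print.point_mass <- function(x, ...) {
  cat(sprintf("<point_mass> fixed at %.4f\n", x$value))
  invisible(x)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single probability strictly inside (0, 1).",
                 name), call. = FALSE)
  }
  invisible(x)
}

# Tail probability P(X > bound) of the Beta implied by a concentration t
# under the given central-tendency parameterization; NA when t is infeasible
# (mode parameterization needs t > 2).
beta_tail_at <- function(t, central, bound, measure) {
  ab <- beta_shapes_at(t, central, measure)
  if (anyNA(ab)) return(NA_real_)
  stats::pbeta(bound, ab[1], ab[2], lower.tail = FALSE)
}

beta_shapes_at <- function(t, central, measure) {
  switch(measure,
    mean = c(central * t, (1 - central) * t),
    mode = {
      if (t <= 2) return(c(NA_real_, NA_real_))
      a <- 1 + central * (t - 2)
      c(a, t - a)
    },
    median = {
      # inner solve: split t into (a, t - a) so the median hits `central`;
      # qbeta(0.5, a, t - a) is strictly increasing in a. qbeta warns about
      # its own accuracy at the extreme shape ratios probed while
      # bracketing; those points are never returned, so the warnings are
      # muted.
      eps <- t * 1e-12
      g <- function(a) {
        suppressWarnings(stats::qbeta(0.5, a, t - a)) - central
      }
      lo <- eps
      hi <- t - eps
      if (g(lo) > 0 || g(hi) < 0) return(c(NA_real_, NA_real_))
      a <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
      c(a, t - a)
    }
  )
}

#' Elicit a Beta prior from a central value and a tail statement
#'
#' Converts an expert statement of the form "the quantity has
#' mean/median/mode `central`, and with probability `prob` it is
#' greater/less than `bound`" into the hyperparameters of a Beta
#' distribution, by root-solving over the concentration `alpha + beta`.
#' The solve is deterministic; the returned prior reproduces both
#' statements to within 1e-6.
#'
#' @param central Central-tendency value in (0, 1).
#' @param bound Tail reference value in (0, 1).
#' @param prob Tail probability in (0, 1): `P(X > bound) = prob` when
#'   `direction = "greater"`, `P(X < bound) = prob` when `"less"`.
#' @param measure Which central-tendency measure `central` states:
#'   `"mean"` (default), `"median"` or `"mode"` (mode requires both shapes
#'   above 1).
#' @param direction `"greater"` (default) or `"less"`.
#' @return A [beta_prior()] carrying the elicitation statement as the
#'   `statement` attribute.
#' @examples
#' elicit_beta(0.8, 0.75, 0.97)   # Beta(195.76, 48.94)
#' elicit_beta(0.5, 0.05, 0.95)   # Beta(1, 1): the uniform prior
#' @export
elicit_beta <- function(central, bound, prob,
                        measure = c("mean", "median", "mode"),
                        direction = c("greater", "less")) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  check_unit_interval(central, "central")
  check_unit_interval(bound, "bound")
  check_unit_interval(prob, "prob")

  # work internally with P(X > bound) = p_greater
  p_greater <- if (direction == "greater") prob else 1 - prob

  lo <- log(1e-6)
  hi <- log(1e8)
  if (measure == "mode") lo <- log(2 + 1e-9)
  h <- function(lt) beta_tail_at(exp(lt), central, bound, measure) - p_greater
  f_lo <- h(lo)
  f_hi <- h(hi)
  if (is.na(f_lo) || is.na(f_hi)) {
    stop("No Beta distribution satisfies the stated constraints.",
         call. = FALSE)
  }
  if (abs(f_lo) < 1e-9 && abs(f_hi) < 1e-9) {
    stop("The elicitation statement is under-determined: every ",
         "concentration satisfies it (e.g. central 0.5 with ",
         "P(X > 0.5) = 0.5). State a bound away from the central value.",
         call. = FALSE)
  }
  if (f_lo * f_hi > 0) {
    stop(sprintf(paste0(
      "Inconsistent elicitation: no Beta with %s %.4g attains ",
      "P(X %s %.4g) = %.4g (attainable tail range is [%.4g, %.4g])."),
      measure, central, if (direction == "greater") ">" else "<", bound,
      prob,
      min(f_lo, f_hi) + p_greater, max(f_lo, f_hi) + p_greater),
      call. = FALSE)
  }
  root <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
  ab <- beta_shapes_at(exp(root), central, measure)
  prior <- beta_prior(ab[1], ab[2])

  # verify both constraints to the promised tolerance
  achieved_central <- switch(measure,
    mean = ab[1] / sum(ab),
    median = stats::qbeta(0.5, ab[1], ab[2]),
    mode = (ab[1] - 1) / (sum(ab) - 2))
  achieved_tail <- stats::pbeta(bound, ab[1], ab[2], lower.tail = FALSE)
  if (abs(achieved_central - central) > 1e-6 ||
      abs(achieved_tail - p_greater) > 1e-6) {
    stop("Elicitation solver failed to reach tolerance 1e-6; the ",
         "constraints are at the edge of feasibility.", call. = FALSE)
  }
  attr(prior, "statement") <- list(measure = measure, central = central,
                                   bound = bound, prob = prob,
                                   direction = direction)
  prior
}

#' Elicit a Gamma prior from its median and 95th percentile
#'
#' Solves for the Gamma shape and rate whose median and 95th percentile
#' equal the stated values. Used for the heterogeneity parameter `psi` of
#' the hierarchical model, mirroring the percentile logic of
#' [elicit_beta()]. The quantile ratio q95/q50 is strictly decreasing in
#' the shape, so the solve is a monotone one-dimensional root find.
#'
#' @param median Target median, positive.
#' @param p95 Target 95th percentile, must exceed `median`.
#' @return A [gamma_prior()].
#' @examples
#' elicit_gamma(log(2), stats::qgamma(0.95, 1, 1))  # recovers Exp(1)
#' @export
elicit_gamma <- function(median, p95) {
  stopifnot(is.numeric(median), is.numeric(p95),
            length(median) == 1L, length(p95) == 1L)
  if (!is.finite(median) || !is.finite(p95) || median <= 0 || p95 <= 0) {
    stop("`median` and `p95` must be finite and positive.", call. = FALSE)
  }
  if (p95 <= median) {
    stop("Inconsistent elicitation: the 95th percentile must exceed the ",
         "median.", call. = FALSE)
  }
  target_ratio <- p95 / median
  h <- function(ls) {
    s <- exp(ls)
    q50 <- stats::qgamma(0.5, s, 1)
    # the unit-rate median underflows for very small shapes, where the
    # quantile ratio is effectively infinite
    if (q50 <= 0) return(Inf)
    log(stats::qgamma(0.95, s, 1)) - log(q50) - log(target_ratio)
  }
  root <- stats::uniroot(h, c(log(1e-8), log(1e8)), tol = 1e-12)$root
  shape <- exp(root)
  rate <- stats::qgamma(0.5, shape, 1) / median
  prior <- gamma_prior(shape, rate)
  if (abs(stats::qgamma(0.5, shape, rate) - median) > 1e-6 * max(1, median) ||
      abs(stats::qgamma(0.95, shape, rate) - p95) > 1e-6 * max(1, p95)) {
    stop("Gamma elicitation failed to reach tolerance.", call. = FALSE)
  }
  prior
}

#' Elicit the hierarchical (mu, psi) prior pair
#'
#' Convenience wrapper for the multi-population model: elicits the Beta
#' prior for the mean prevalence `mu` from a percentile statement and the
#' Gamma prior for the concentration `psi` from (median, 95th percentile)
#' statements.
#'
#' @inheritParams elicit_beta
#' @param psi_median,psi_p95 Median and 95th percentile stated for `psi`.
#' @return A list with components `mu` ([beta_prior()]) and `psi`
#'   ([gamma_prior()]).
#' @export
elicit_hierarchical <- function(central, bound, prob,
                                measure = c("mean", "median", "mode"),
                                direction = c("greater", "less"),
                                psi_median, psi_p95) {
  list(mu = elicit_beta(central, bound, prob, measure, direction),
       psi = elicit_gamma(psi_median, psi_p95))
}

#' Summarize a prior distribution
#'
#' Exact mean and quantiles (2.5%, 25%, 50%, 75%, 97.5%) of a Beta or
#' Gamma prior, computed from the distribution function.
#'
#' @param prior A [beta_prior()] or [gamma_prior()].
#' @return A one-row tibble with columns `mean`, `median`, `q2_5`, `q25`,
#'   `q75`, `q97_5`.
#' @export
summarize_prior <- function(prior) {
  UseMethod("summarize_prior")
}

#' @export
summarize_prior.beta_prior <- function(prior) {
  q <- stats::qbeta(c(0.025, 0.25, 0.5, 0.75, 0.975),
                    prior$alpha, prior$beta)
  tibble::tibble(mean = prior$alpha / (prior$alpha + prior$beta),
                 median = q[3], q2_5 = q[1], q25 = q[2], q75 = q[4],
                 q97_5 = q[5])
}

#' @export
summarize_prior.gamma_prior <- function(prior) {
  q <- stats::qgamma(c(0.025, 0.25, 0.5, 0.75, 0.975),
                     prior$shape, prior$rate)
  tibble::tibble(mean = prior$shape / prior$rate,
                 median = q[3], q2_5 = q[1], q25 = q[2], q75 = q[4],
                 q97_5 = q[5])
}

#' @export
summarize_prior.point_mass <- function(prior) {
  tibble::tibble(mean = prior$value, median = prior$value,
                 q2_5 = prior$value, q25 = prior$value, q75 = prior$value,
                 q97_5 = prior$value)
}

#' Tabulate a prior density
#'
#' Emits an (x, density) table for plotting a Beta or Gamma prior.
#'
#' @param prior A [beta_prior()] or [gamma_prior()].
#' @param n Number of grid points.
#' @return A tibble with columns `x` and `density`.
#' @export
prior_density_table <- function(prior, n = 512) {
  if (inherits(prior, "beta_prior")) {
    x <- seq(1e-4, 1 - 1e-4, length.out = n)
    d <- stats::dbeta(x, prior$alpha, prior$beta)
  } else if (inherits(prior, "gamma_prior")) {
    x <- seq(1e-6, stats::qgamma(0.999, prior$shape, prior$rate),
             length.out = n)
    d <- stats::dgamma(x, prior$shape, prior$rate)
  } else {
    stop("Unsupported prior type.", call. = FALSE)
  }
  tibble::tibble(x = x, density = d)
}
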