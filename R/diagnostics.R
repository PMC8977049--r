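#' Effective sample size
#'
#' Geyer initial-positive-sequence estimator computed per chain and summed
#' across chains: the integrated autocorrelation time
#' `tau = 1 + 2 * sum(rho_l)` is estimated by summing successive pairs of
#' sample autocorrelations until a pair sum turns negative, and each chain
#' contributes `n / tau` effective draws. A chain with (numerically) zero
#' variance contributes the estimator floor of 1.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @return Effective number of independent draws, capped at the total
#'   retained draw count.
#' @export
effective_sample_size <- function(fit, parameter) {
  m <- param_matrix(fit, parameter)
  n <- nrow(m)
  if (n < 100L) stop("Need at least 100 retained draws per chain.",
                     call. = FALSE)
  ess <- sum(apply(m, 2, chain_ess))
  min(ess, n * ncol(m))
}

chain_ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v < .Machine$double.eps) return(1)
  lag_max <- min(n - 1L, 2000L)
  rho <- as.vector(stats::acf(x, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)  # rho[1] is lag 0
  tau <- 1
  l <- 2L
  while (l + 1L <= length(rho)) {
    pair <- rho[l] + rho[l + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    l <- l + 2L
  }
  n / max(tau, 1)
}

#' Potential scale reduction (shrink factor)
#'
#' Split-chain between/within variance ratio: each chain is halved, and
#' with m resulting sequences of length n the factor is
#' `sqrt(((n-1)/n * W + B/n) / W)` where B is n times the variance of the
#' sequence means and W the mean of the sequence variances. Splitting also
#' exposes within-chain drift (a first half that disagrees with the second
#' half inflates the factor the same way disagreeing chains do). Values
#' near 1 indicate convergence.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @return The shrink factor (>= 1 up to numerical noise; `Inf` for
#'   disjoint degenerate chains; 1 for fully constant draws).
#' @export
shrink_factor <- function(fit, parameter) {
  m <- param_matrix(fit, parameter)
  if (nrow(m) < 4L) stop("Need at least 4 retained draws per chain.",
                         call. = FALSE)
  split_rhat(m)
}

split_rhat <- function(m) {
  n_half <- nrow(m) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(n_half), j], m[n_half + seq_len(n_half), j])
  }))
  mu_j <- colMeans(halves)
  var_j <- apply(halves, 2, stats::var)
  B <- n_half * stats::var(mu_j)
  W <- mean(var_j)
  if (!is.finite(W) || W < .Machine$double.eps) {
    return(if (B < .Machine$double.eps) 1 else Inf)
  }
  # the raw ratio can dip just below 1 by sampling noise; floor it so the
  # reported factor is always >= 1
  max(1, sqrt(((n_half - 1) / n_half * W + B / n_half) / W))
}

#' Autocorrelation series of a parameter's chains
#'
#' Per-chain sample autocorrelations averaged across chains. Lag 0 is 1 by
#' definition. For a degenerate (constant) chain the autocorrelation is
#' reported as 0 at all positive lags with `degenerate = TRUE`, so report
#' generation never fails on a stuck or fixed parameter.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @param max_lag Largest lag (must be below the per-chain draw count).
#' @return A tibble with columns `lag`, `autocorrelation`, `degenerate`.
#' @export
autocorrelation_series <- function(fit, parameter, max_lag = 40) {
  m <- param_matrix(fit, parameter)
  if (max_lag >= nrow(m)) stop("`max_lag` must be below the per-chain draw ",
                               "count.", call. = FALSE)
  per_chain <- apply(m, 2, function(x) {
    if (stats::var(x) < .Machine$double.eps) {
      c(1, rep(0, max_lag))
    } else {
      as.vector(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf)
    }
  })
  degenerate <- any(apply(m, 2, stats::var) < .Machine$double.eps)
  tibble::tibble(lag = 0:max_lag,
                 autocorrelation = rowMeans(per_chain),
                 degenerate = degenerate)
}

#' Running (ergodic) mean series
#'
#' Cumulative mean of each chain at every retained iteration; the visual
#' convergence check that the chain mean settles quickly.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @return A tibble with columns `chain`, `iteration`, `running_mean`.
#' @export
running_mean_series <- function(fit, parameter) {
  m <- param_matrix(fit, parameter)
  purrr::map_dfr(seq_len(ncol(m)), function(ch) {
    x <- m[, ch]
    tibble::tibble(chain = ch, iteration = seq_along(x),
                   running_mean = cumsum(x) / seq_along(x))
  })
}

#' Chain density tables (full and partial chains)
#'
#' Gaussian-kernel density of each chain's draws, and of each half of each
#' chain, on a common 512-point grid with a single rule-of-thumb
#' (Silverman) bandwidth computed from the pooled draws — so the curves of
#' different chains and chain halves are directly comparable, as in the
#' complete-versus-partial-chain convergence plots.
#'
#' @param fit A [fit_prevalence()] result.
#' @param parameter Parameter name.
#' @param grid_n Number of grid points.
#' @return A tibble with columns `parameter`, `chain`, `segment`
#'   (`"full"`, `"first_half"`, `"second_half"`), `x`, `density`.
#' @export
density_tables <- function(fit, parameter, grid_n = 512) {
  m <- param_matrix(fit, parameter)
  pooled <- as.vector(m)
  bw <- stats::bw.nrd0(pooled)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-6, stats::sd(pooled), 1e-6)
  from <- min(pooled) - 3 * bw
  to <- max(pooled) + 3 * bw
  n_half <- nrow(m) %/% 2L
  segs <- list(full = seq_len(nrow(m)),
               first_half = seq_len(n_half),
               second_half = n_half + seq_len(n_half))
  purrr::map_dfr(seq_len(ncol(m)), function(ch) {
    purrr::map_dfr(names(segs), function(sg) {
      dd <- stats::density(m[segs[[sg]], ch], bw = bw, from = from, to = to,
                           n = grid_n)
      tibble::tibble(parameter = parameter, chain = ch, segment = sg,
                     x = dd$x, density = dd$y)
    })
  })
}

#' Convergence diagnostics for every parameter
#'
#' @param fit A [fit_prevalence()] result.
#' @return A tibble with one row per parameter: effective sample size and
#'   split-chain shrink factor.
#' @export
mcmc_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "prev_fit"))
  purrr::map_dfr(fit$parameters, function(p) {
    tibble::tibble(parameter = p,
                   ess = effective_sample_size(fit, p),
                   shrink_factor = shrink_factor(fit, p))
  })
}
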