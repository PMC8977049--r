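# Percentile-based elicitation of Beta and Gamma hyperparameters.

test_that("mean-parameterized elicitation reproduces published priors", {
  cases <- list(
    # central, bound, prob, expected alpha, expected beta
    list(0.8, 0.75, 0.97, 195.76, 48.94),   # sensitivity, toy setups
    list(0.9, 0.85, 0.97, 135.86, 15.10),   # specificity, toy setups
    list(0.5, 0.05, 0.95, 1.00, 1.00),      # uniform prevalence prior
    list(0.5, 0.08, 0.95, 1.31, 1.31),      # slightly peaked prevalence
    list(0.88, 0.80, 0.90, 25.88, 3.53),    # dementia sensitivity
    list(0.95, 0.85, 0.97, 25.63, 1.35))    # dementia specificity
  for (cs in cases) {
    p <- elicit_beta(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(round(p$alpha, 2), cs[[4]], tolerance = 1e-8)
    expect_equal(round(p$beta, 2), cs[[5]], tolerance = 1e-8)
  }
})

test_that("elicited Beta priors satisfy both statements to 1e-6 (round trip)", {
  grid <- expand.grid(central = c(0.1, 0.3, 0.5, 0.8, 0.95),
                      gap = c(0.3, 0.6), pfrac = c(0.3, 0.6, 0.9))
  for (i in seq_len(nrow(grid))) {
    m <- grid$central[i]
    v <- m * (1 - grid$gap[i])      # bound below the mean
    # attainable tail probabilities lie in (m, 1); pick one inside
    p <- m + (1 - m) * grid$pfrac[i]
    pr <- elicit_beta(m, v, p)
    expect_equal(pr$alpha / (pr$alpha + pr$beta), m, tolerance = 1e-6)
    expect_equal(pbeta(v, pr$alpha, pr$beta, lower.tail = FALSE), p,
                 tolerance = 1e-6)
  }
})

test_that("median and mode parameterizations hit their stated measures", {
  pm <- elicit_beta(0.88, 0.80, 0.90, measure = "median")
  expect_equal(qbeta(0.5, pm$alpha, pm$beta), 0.88, tolerance = 1e-6)
  expect_equal(pbeta(0.80, pm$alpha, pm$beta, lower.tail = FALSE), 0.90,
               tolerance = 1e-6)

  po <- elicit_beta(0.3, 0.1, 0.95, measure = "mode")
  expect_gt(po$alpha, 1)
  expect_gt(po$beta, 1)
  expect_equal((po$alpha - 1) / (po$alpha + po$beta - 2), 0.3,
               tolerance = 1e-6)
  expect_equal(pbeta(0.1, po$alpha, po$beta, lower.tail = FALSE), 0.95,
               tolerance = 1e-6)
})

test_that("'less' direction statements are honoured", {
  p <- elicit_beta(0.2, 0.4, 0.99, direction = "less")
  expect_equal(p$alpha / (p$alpha + p$beta), 0.2, tolerance = 1e-6)
  expect_equal(pbeta(0.4, p$alpha, p$beta), 0.99, tolerance = 1e-6)
})

test_that("solver agrees with an independent grid-refinement oracle", {
  # iterative grid search over the concentration t = alpha + beta,
  # refining the bracket three times; no root finder involved
  grid_solve <- function(m, v, p) {
    lo <- log(1e-6); hi <- log(1e8)
    for (round in 1:4) {
      ts <- exp(seq(lo, hi, length.out = 801))
      tail <- pbeta(v, m * ts, (1 - m) * ts, lower.tail = FALSE)
      i <- which.min(abs(tail - p))
      lo <- log(ts[max(1, i - 1)]); hi <- log(ts[min(length(ts), i + 1)])
    }
    exp((lo + hi) / 2)
  }
  for (cs in list(c(0.8, 0.75, 0.97), c(0.3, 0.1, 0.9), c(0.5, 0.05, 0.95))) {
    pr <- elicit_beta(cs[1], cs[2], cs[3])
    t_grid <- grid_solve(cs[1], cs[2], cs[3])
    tail_grid <- pbeta(cs[2], cs[1] * t_grid, (1 - cs[1]) * t_grid,
                       lower.tail = FALSE)
    tail_solver <- pbeta(cs[2], pr$alpha, pr$beta, lower.tail = FALSE)
    expect_equal(tail_solver, tail_grid, tolerance = 1e-6)
  }
})

test_that("tighter tail statements give more concentrated priors", {
  conc <- sapply(c(0.80, 0.90, 0.95, 0.99), function(p) {
    pr <- elicit_beta(0.5, 0.3, p)
    pr$alpha + pr$beta
  })
  expect_true(all(diff(conc) > 0))
})

test_that("inconsistent and under-determined statements are rejected", {
  # mean 0.5 but 97% sure above 0.7: unattainable under any concentration
  expect_error(elicit_beta(0.5, 0.7, 0.97), "Inconsistent")
  # symmetric fixed point: every alpha = beta satisfies it
  expect_error(elicit_beta(0.5, 0.5, 0.5), "under-determined")
  # domain errors
  expect_error(elicit_beta(1.2, 0.5, 0.9), "inside \\(0, 1\\)")
  expect_error(elicit_beta(0.5, 0, 0.9), "inside \\(0, 1\\)")
})

test_that("Gamma elicitation recovers the exponential special case and inverts", {
  g <- elicit_gamma(log(2), qgamma(0.95, 1, 1))
  expect_equal(g$shape, 1, tolerance = 1e-6)
  expect_equal(g$rate, 1, tolerance = 1e-6)

  g2 <- elicit_gamma(0.693, 2.996)
  expect_equal(qgamma(0.5, g2$shape, g2$rate), 0.693, tolerance = 1e-6)
  expect_equal(qgamma(0.95, g2$shape, g2$rate), 2.996, tolerance = 1e-6)
})

test_that("Gamma elicitation verified by quadrature of its own density", {
  g <- elicit_gamma(5, 15)
  # oracle: integrate the density up to the claimed quantiles
  mass_to <- function(q) integrate(function(x) dgamma(x, g$shape, g$rate),
                                   0, q, rel.tol = 1e-10)$value
  expect_equal(mass_to(5), 0.5, tolerance = 1e-7)
  expect_equal(mass_to(15), 0.95, tolerance = 1e-7)
  expect_error(elicit_gamma(5, 5), "must exceed")
})

test_that("hierarchical elicitation delegates componentwise", {
  h <- elicit_hierarchical(0.2, 0.05, 0.95, psi_median = 5, psi_p95 = 15)
  expect_s3_class(h$mu, "beta_prior")
  expect_s3_class(h$psi, "gamma_prior")
  expect_equal(h$mu$alpha / (h$mu$alpha + h$mu$beta), 0.2, tolerance = 1e-6)
  # mean of Beta(mu*psi, psi*(1-mu)) at any (mu, psi) equals mu
  mu_mean <- h$mu$alpha / (h$mu$alpha + h$mu$beta)
  psi_mean <- h$psi$shape / h$psi$rate
  a <- mu_mean * psi_mean; b <- psi_mean * (1 - mu_mean)
  expect_equal(a / (a + b), mu_mean, tolerance = 1e-12)
})

test_that("prior summaries order their quantiles and match known cases", {
  s <- summarize_prior(beta_prior(1, 1))
  expect_equal(s$median, 0.5)
  expect_equal(s$q25, 0.25)
  expect_equal(s$q75, 0.75)

  s2 <- summarize_prior(beta_prior(0.14, 0.55))
  expect_true(s2$q2_5 <= s2$q25 && s2$q25 <= s2$median &&
                s2$median <= s2$q75 && s2$q75 <= s2$q97_5)
  # exact quantiles of this bathtub-shaped prior
  expect_equal(s2$median, qbeta(0.5, 0.14, 0.55), tolerance = 1e-9)

  s3 <- summarize_prior(elicit_beta(0.88, 0.80, 0.90))
  expect_equal(s3$median, 0.88, tolerance = 0.01)

  s4 <- summarize_prior(gamma_prior(2, 4))
  expect_equal(s4$mean, 0.5)
  expect_true(all(diff(unlist(s4[c("q2_5", "q25", "median", "q75",
                                   "q97_5")])) >= 0))
})
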