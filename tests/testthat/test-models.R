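# Likelihoods, conjugate updates, the apparent/true map, Wald intervals.

test_that("conjugate apparent-prevalence posterior is Beta(a+y, b+n-y)", {
  p1 <- apparent_posterior(survey_counts(0, 1), beta_prior(1, 1))
  expect_equal(c(p1$alpha, p1$beta), c(1, 2))
  p2 <- apparent_posterior(survey_counts(120, 500), beta_prior(1, 1))
  expect_equal(c(p2$alpha, p2$beta), c(121, 381))
  # posterior mean recomputed by quadrature of the Beta density
  m <- integrate(function(x) x * dbeta(x, 121, 381), 0, 1,
                 rel.tol = 1e-10)$value
  expect_equal(summarize_prior(p2)$mean, m, tolerance = 1e-8)
  expect_equal(m, 121 / 502, tolerance = 1e-8)
})

test_that("the apparent-true prevalence map is affine with known boundaries", {
  expect_equal(rogan_gladen(0, 0.8, 0.9), 0.1)    # only false positives
  expect_equal(rogan_gladen(1, 0.8, 0.9), 0.8)    # only true positives
  expect_equal(rogan_gladen(0.2015, 0.80, 0.90), 0.24105, tolerance = 1e-12)
  # algebraic inverse recovers the true prevalence when Se + Sp > 1
  pa <- rogan_gladen(0.2014, 0.80, 0.90)
  expect_equal((pa - 0.1) / 0.7, 0.2014, tolerance = 1e-12)
  # increasing in pi_t when Se + Sp > 1, decreasing when Se + Sp < 1
  pts <- seq(0, 1, by = 0.1)
  expect_true(all(diff(rogan_gladen(pts, 0.9, 0.8)) > 0))
  expect_true(all(diff(rogan_gladen(pts, 0.4, 0.5)) < 0))
})

test_that("model specification validates prior/family combinations", {
  expect_error(prev_model("true_single", prevalence_prior = beta_prior(1, 1)),
               "se_prior")
  expect_error(prev_model("apparent_single", prevalence_prior = beta_prior(1, 1),
                          se_prior = beta_prior(2, 2),
                          sp_prior = beta_prior(2, 2)),
               "do not apply")
  expect_error(prev_model("apparent_single", prevalence_prior = beta_prior(1, 1),
                          zero_inflated = TRUE),
               "w_prior")
  expect_warning(prev_model("true_single", prevalence_prior = beta_prior(1, 1),
                            se_prior = point_mass(0.4),
                            sp_prior = point_mass(0.5)),
                 "identified")
})

# independent oracle: P(y) by explicit enumeration of the latent 2x2
# classification (true status x test result)
enumeration_pmf <- function(y, n, pi_t, se, sp) {
  total <- 0
  for (d in 0:n) {                      # d truly diseased subjects
    p_d <- dbinom(d, n, pi_t)
    p_y_given_d <- 0
    for (j in max(0, y - (n - d)):min(d, y)) {   # j true positives
      p_y_given_d <- p_y_given_d +
        dbinom(j, d, se) * dbinom(y - j, n - d, 1 - sp)
    }
    total <- total + p_d * p_y_given_d
  }
  total
}

test_that("single-population log-likelihood matches latent-class enumeration", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(3:10, 1)
    y <- sample(0:n, 1)
    pi_t <- runif(1, 0.05, 0.95)
    se <- runif(1, 0.6, 0.99)
    sp <- runif(1, 0.6, 0.99)
    expect_equal(loglik_true_single(pi_t, se, sp, survey_counts(y, n)),
                 log(enumeration_pmf(y, n, pi_t, se, sp)),
                 tolerance = 1e-10)
  }
  # perfect test reduces to the apparent-prevalence likelihood
  expect_equal(loglik_true_single(0.3, 1, 1, survey_counts(0, 1)),
               log(1 - 0.3), tolerance = 1e-12)
  # closed form at success probability 1/2
  expect_equal(loglik_true_single(0.5, 0.5, 0.5, survey_counts(3, 10)),
               log(choose(10, 3)) - 10 * log(2), tolerance = 1e-12)
})

test_that("multi-population log-likelihood is the sum of per-cluster terms", {
  set.seed(7)
  tab <- validate_cluster_table(
    tibble::tibble(positive = c(3, 0, 11), n = c(20, 15, 40)))
  pi_t <- c(0.1, 0.02, 0.4)
  total <- loglik_true_multi(pi_t, 0.9, 0.95, tab)
  per_row <- sum(sapply(1:3, function(i) {
    loglik_true_single(pi_t[i], 0.9, 0.95,
                       survey_counts(tab$positive[i], tab$n[i]))
  }))
  expect_equal(total, per_row, tolerance = 1e-12)
  # k = 1 reduces to the single-population likelihood
  one <- validate_cluster_table(tibble::tibble(positive = 3, n = 20))
  expect_equal(loglik_true_multi(0.1, 0.9, 0.95, one),
               loglik_true_single(0.1, 0.9, 0.95, survey_counts(3, 20)))
  # all-zero counts with a perfect test: sum n_i * log(1 - pi_ti)
  z <- validate_cluster_table(tibble::tibble(positive = c(0, 0), n = c(5, 9)))
  expect_equal(loglik_true_multi(c(0.2, 0.3), 1, 1, z),
               5 * log(0.8) + 9 * log(0.7), tolerance = 1e-12)
  expect_error(loglik_true_multi(c(0.1, 0.2), 0.9, 0.95, one), "per cluster")
})

test_that("hierarchical prior has mean mu and variance shrinking in psi", {
  # Beta(mu*psi, psi*(1-mu)) variance identity
  v <- function(mu, psi) mu * (1 - mu) / (psi + 1)
  expect_true(all(diff(sapply(c(1, 5, 20, 100), v, mu = 0.3)) < 0))
  # mu = 0.5, psi = 2 is the uniform: log-density 0 everywhere
  expect_equal(log_hier_prior(c(0.1, 0.5, 0.93), 0.5, 2), 0,
               tolerance = 1e-12)
  # sampling oracle: draws at (0.2, 10) average to 0.2
  set.seed(11)
  draws <- rbeta(200000, 0.2 * 10, 10 * 0.8)
  expect_lt(abs(mean(draws) - 0.2), 0.005)
  expect_lt(abs(var(draws) - v(0.2, 10)), 0.001)
  expect_equal(log_hier_prior(0.5, 0.5, 2), 0)
  expect_identical(log_hier_prior(c(0, 0.5), 0.3, 5), -Inf)
})

test_that("mixture likelihood marginalizes the free/infected indicator", {
  d <- survey_counts(4, 30)
  # w -> 1 recovers the non-mixture likelihood
  expect_equal(mixture_loglik(0.2, 1 - 1e-12, d, se = 0.9, sp = 0.95),
               loglik_true_single(0.2, 0.9, 0.95, d), tolerance = 1e-9)
  # enumeration oracle over the latent indicator
  naive <- log(0.3 * exp(loglik_true_single(0.2, 0.9, 0.95, d)) +
                 0.7 * dbinom(4, 30, 1 - 0.95))
  expect_equal(mixture_loglik(0.2, 0.3, d, se = 0.9, sp = 0.95), naive,
               tolerance = 1e-10)
  # positives with a perfect specificity kill the free component
  d2 <- survey_counts(2, 10)
  expect_equal(mixture_loglik(0.3, 0.4, d2, se = 0.9, sp = 1 - 1e-12),
               log(0.4) + loglik_true_single(0.3, 0.9, 1 - 1e-12, d2),
               tolerance = 1e-6)
  # apparent family: free component only possible with zero positives
  expect_equal(mixture_loglik(0.3, 0.4, survey_counts(0, 10),
                              family = "apparent_single"),
               log(0.4 * dbinom(0, 10, 0.3) + 0.6), tolerance = 1e-12)
  # multi-population: mixture applies independently per cluster
  tab <- validate_cluster_table(
    tibble::tibble(positive = c(2, 0), n = c(10, 12)))
  manual <- sum(sapply(1:2, function(i) {
    log(0.4 * exp(loglik_true_single(c(0.15, 0.05)[i], 0.9, 0.95,
                                     survey_counts(tab$positive[i], tab$n[i]))) +
          0.6 * dbinom(tab$positive[i], tab$n[i], 0.05))
  }))
  expect_equal(mixture_loglik(c(0.15, 0.05), 0.4, tab, se = 0.9, sp = 0.95,
                              family = "true_multi"),
               manual, tolerance = 1e-10)
})

test_that("Wald intervals reproduce the nine published study rows exactly", {
  dem <- load_fixture("dementia_9")
  printed <- tibble::tribble(
    ~estimate, ~lower, ~upper,
    0.062, 0.047, 0.078,
    0.060, 0.049, 0.072,
    0.094, 0.080, 0.108,
    0.053, 0.042, 0.064,
    0.058, 0.052, 0.064,
    0.321, 0.290, 0.351,
    0.085, 0.073, 0.097,
    0.357, 0.339, 0.376,
    0.038, 0.028, 0.049)
  w <- wald_interval(dem, level = 0.95)
  expect_equal(round(w$estimate, 3), printed$estimate)
  expect_equal(round(w$lower, 3), printed$lower)
  expect_equal(round(w$upper, 3), printed$upper)
  # degenerate all-negative survey collapses to a zero-width interval at 0
  z <- wald_interval(survey_counts(0, 50))
  expect_equal(c(z$estimate, z$lower, z$upper), c(0, 0, 0))
})
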