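test_that("Box-Cox link hits its landmark values and log limit", {
  expect_equal(eee_link(1, 2), 3)
  expect_equal(eee_link(0.5, 2), 4)
  expect_equal(eee_link(1e-8, 2), exp(2), tolerance = 1e-6)
  expect_error(eee_link(1, c(1, -2)), "domain")
})

test_that("EEE recovers the link parameter from sqrt- and log-link DGPs", {
  d_sqrt <- gamma_sqrt_data(10000, alpha = 3, seed = 61)
  fit <- fit_eee(d_sqrt)
  expect_true(fit$converged)
  expect_lt(abs(fit$lam - 0.5), 0.1)

  d_log <- lognormal_data(10000,
                          beta = c(5.5, 0.9, 0, 0, 0.5, 0, 0, 0, 0.5, 0.4),
                          sigma = 0.8, seed = 63)
  fit2 <- fit_eee(d_log)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$lam - 0), 0.1)
})

test_that("EEE with fixed (lambda, theta2) reproduces the quasi-GLM mean fit", {
  d <- gamma_sqrt_data(2000, alpha = 2, seed = 65)
  eee <- fit_eee(d, lam = 0.5, theta2 = 1)
  glm_fit <- fit_glm(d, "sqrt", 1)
  expect_equal(predict_eee(eee, d$X), predict_mean(glm_fit, d$X),
               tolerance = 1e-5)
})

test_that("mixture loglik collapses exactly in degenerate cases", {
  d <- gamma_log_data(200, beta = c(1.5, 0.3), alpha = 2, seed = 71)
  k <- ncol(d$X)
  b <- c(1.5, 0.3, rep(0, k - 2))
  single <- sum(stats::dgamma(d$y, shape = 2, scale = exp(drop(d$X %*% b)),
                              log = TRUE))
  # two identical components: any pi
  p_id <- list(pi = c(0.3, 0.7), alpha = c(2, 2), betas = cbind(b, b),
               link = "log")
  expect_equal(fmm_loglik(p_id, d), single, tolerance = 1e-10)
  # pi = (1, 0)
  p10 <- list(pi = c(1, 1e-300), alpha = c(2, 5),
              betas = cbind(b, rep(1, k)), link = "log")
  expect_equal(fmm_loglik(p10, d), single, tolerance = 1e-8)
})

test_that("mixture density integrates to 1", {
  f <- function(y) {
    0.6 * stats::dgamma(y, shape = 2, scale = exp(1)) +
      0.4 * stats::dgamma(y, shape = 0.7, scale = exp(2.5))
  }
  expect_equal(quad01(f), 1, tolerance = 1e-8)
  # and fmm_loglik agrees with the same mixture density pointwise
  y <- c(0.5, 3, 20)
  d <- cost_dataset(matrix(1, 3, 1), y)
  par <- list(pi = c(0.6, 0.4), alpha = c(2, 0.7), betas = cbind(1, 2.5),
              link = "log")
  expect_equal(fmm_loglik(par, d), sum(log(f(y))), tolerance = 1e-10)
})

test_that("mixture conditional means follow the weighted component formula", {
  X1 <- matrix(1, 1, 1)
  # log link, indices (0, 0): 0.5*1*1 + 0.5*2*1 = 1.5
  expect_equal(unname(fmm_mean(list(pi = c(0.5, 0.5), alpha = c(1, 2),
                                    betas = cbind(0, 0), link = "log"), X1)),
               1.5)
  # sqrt link, indices (1, 2): 0.5*1*1 + 0.5*2*4 = 4.5
  expect_equal(unname(fmm_mean(list(pi = c(0.5, 0.5), alpha = c(1, 2),
                                    betas = cbind(1, 2), link = "sqrt"), X1)),
               4.5)
  # pi = (1, 0) reduces to component 1
  expect_equal(unname(fmm_mean(list(pi = c(1, 0), alpha = c(3, 9),
                                    betas = cbind(0.4, 2), link = "log"), X1)),
               3 * exp(0.4))
})

test_that("mixture mean matches Monte Carlo draws from the mixture", {
  X <- matrix(1, 1, 1)
  par <- list(pi = c(0.7, 0.3), alpha = c(1.5, 4), betas = cbind(0.5, 1.8),
              link = "log")
  m_cf <- unname(fmm_mean(par, X))
  n <- 200000
  cfg <- dgp_config("gamma_mixture", link = "log",
                    coefficients = cbind(0.5, 1.8),
                    shape = list(pi = c(0.7, 0.3), alpha = c(1.5, 4)),
                    seed = 77)
  y <- simulate_costs(matrix(1, n, 1), cfg)$y
  expect_lt(abs(mean(y) - m_cf), 3 * stats::sd(y) / sqrt(n))
})

test_that("EM recovers a well-separated two-component log-link mixture", {
  X <- tiny_design(10000, seed = 81)
  k <- ncol(X)
  b1 <- c(0.5, 0.2, rep(0, k - 2))
  b2 <- c(3.0, -0.2, rep(0, k - 2))
  cfg <- dgp_config("gamma_mixture", link = "log", coefficients = cbind(b1, b2),
                    shape = list(pi = c(0.7, 0.3), alpha = c(2, 2)), seed = 82)
  d <- simulate_costs(X, cfg)
  fit <- fit_fmm(d, "log", seed = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi[1] - 0.7), 0.05)
  true_m <- c(mean(2 * exp(drop(X %*% b1))), mean(2 * exp(drop(X %*% b2))))
  est_m <- vapply(1:2, function(j) {
    mean(fit$alpha[j] * exp(drop(X %*% fit$betas[, j])))
  }, numeric(1))
  expect_lt(abs(est_m[1] / true_m[1] - 1), 0.05)
  expect_lt(abs(est_m[2] / true_m[2] - 1), 0.05)
  # EM ascent property
  expect_true(all(diff(fit$ll_trace) > -1e-6))
})

test_that("mixture fit is invariant to start-component permutations and nests the single gamma", {
  d <- gamma_log_data(2000, beta = c(1.8, 0.4), alpha = 2, seed = 91)
  f1 <- fit_fmm(d, "log", seed = 1)
  f2 <- fit_fmm(d, "log", seed = 9)
  # canonical component order: ascending mean
  m1 <- fmm_mean(f1, d$X); m2 <- fmm_mean(f2, d$X)
  expect_lt(mean(abs(m1 - m2)) / mean(d$y), 0.01)
  # single gamma is nested: mixture loglik cannot fall below it
  gfit <- fit_glm(d, "log", 2)
  mu <- predict_mean(gfit, d$X)
  rhs <- 1 + mean(log(d$y / mu) - d$y / mu)
  a_hat <- costreg:::solve_gamma_shape(rhs)
  ll_single <- sum(stats::dgamma(d$y, shape = a_hat, scale = mu / a_hat,
                                 log = TRUE))
  expect_gte(f1$loglik, ll_single - 1e-3)
})
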