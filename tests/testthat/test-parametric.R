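# Quadrature oracles for the parametric families: densities must integrate
# to 1 and closed-form conditional means must match numerical integrals.

dgg <- function(y, logb, sigma, kappa) exp(costreg:::dgg_log(y, logb, sigma, kappa))
dgb2 <- function(y, b, a, p, q) exp(costreg:::dgb2_log(y, b, a, p, q))

test_that("generalized gamma density integrates to 1 and matches its mean", {
  grid <- list(c(0.8, 0.5), c(0.7, 0.3), c(1.2, 1.5), c(0.5, 1))
  for (g in grid) {
    s <- g[1]; k <- g[2]
    expect_equal(quad01(dgg, logb = 0.3, sigma = s, kappa = k), 1,
                 tolerance = 1e-6, label = sprintf("sigma=%g kappa=%g", s, k))
    m_quad <- quad01(function(y) y * dgg(y, 0.3, s, k))
    m_cf <- mean_gg(list(beta = 0.3, sigma = s, kappa = k), matrix(1, 1, 1))
    expect_equal(m_cf, m_quad, tolerance = 1e-6)
  }
})

test_that("generalized gamma special cases are exact", {
  # kappa = sigma = 1, zero index: unit exponential; loglik at y = 1 is -1
  d1 <- cost_dataset(matrix(1, 1, 1), 1)
  expect_equal(loglik_gg(list(beta = 0, sigma = 1, kappa = 1), d1), -1)
  expect_equal(unname(mean_gg(list(beta = 2, sigma = 1, kappa = 1),
                              matrix(1, 1, 1))), exp(2))
  # kappa -> 0 approaches the lognormal
  y <- c(0.5, 1.3, 4)
  d <- cost_dataset(matrix(1, 3, 1), y)
  s2 <- 2 * log(2)
  ll_gg <- loglik_gg(list(beta = 0, sigma = sqrt(s2), kappa = 1e-4), d)
  ll_ln <- sum(stats::dlnorm(y, 0, sqrt(s2), log = TRUE))
  expect_lt(abs(ll_gg - ll_ln), 1e-3)
  expect_equal(unname(mean_gg(list(beta = 0, sigma = sqrt(s2), kappa = 1e-4),
                              matrix(1, 1, 1))), 2, tolerance = 1e-6)
})

test_that("generalized gamma density agrees with an independent implementation", {
  skip_if_not_installed("flexsurv")
  y <- c(0.2, 1, 3.7, 10)
  ours <- costreg:::dgg_log(y, logb = 0.5, sigma = 0.8, kappa = 0.6)
  ref <- flexsurv::dgengamma(y, mu = 0.5, sigma = 0.8, Q = 0.6, log = TRUE)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("GB2 density integrates to 1 and matches its mean", {
  grid <- list(c(2, 1.5, 2.5), c(1, 2, 3), c(0.8, 1.2, 2.2), c(3, 0.7, 1.4))
  for (g in grid) {
    a <- g[1]; p <- g[2]; q <- g[3]
    expect_equal(quad01(dgb2, b = 1.7, a = a, p = p, q = q), 1,
                 tolerance = 1e-6, label = sprintf("a=%g p=%g q=%g", a, p, q))
    if (q > 1 / a) {
      m_quad <- quad01(function(y) y * dgb2(y, 1.7, a, p, q))
      m_cf <- mean_gb2(list(a = a, p = p, q = q, link = "log",
                            beta = log(1.7)), matrix(1, 1, 1))
      expect_equal(m_cf, m_quad, tolerance = 1e-6)
    }
  }
})

test_that("GB2 mean formula special cases and domain error", {
  expect_equal(unname(mean_gb2(list(a = 1, p = 2, q = 3, link = "log",
                                    beta = 0), matrix(1, 1, 1))), 1)
  expect_equal(unname(mean_gb2(list(a = 1, p = 1, q = 2, link = "log",
                                    beta = log(5)), matrix(1, 1, 1))), 5)
  expect_error(mean_gb2(list(a = 1, p = 1, q = 0.9, link = "log", beta = 0),
                        matrix(1, 1, 1)), "undefined")
})

test_that("lognormal ML equals least squares on logs", {
  d <- lognormal_data(800, beta = c(2, 0.4, -0.1), sigma = 0.7, seed = 41)
  fit <- fit_lognormal(d)
  ols <- stats::lm.fit(d$X, log(d$y))
  expect_equal(fit$beta, ols$coefficients)
  expect_equal(fit$sigma, sqrt(mean(ols$residuals^2)))
})

test_that("generalized gamma ML recovers its own DGP within 3 SEs", {
  X <- tiny_design(5000, seed = 43)
  beta <- c(2, 0.4, 0, 0, -0.3, rep(0, ncol(X) - 5))
  d <- simulate_costs(X, dgp_config("generalized_gamma", coefficients = beta,
                                    shape = list(sigma = 0.8, kappa = 0.5),
                                    seed = 44))
  fit <- fit_gg(d)
  expect_true(fit$converged)
  k <- ncol(X)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta - beta) < 3 * se[1:k]))
  # sigma was optimized on the log scale: delta method
  expect_lt(abs(log(fit$sigma) - log(0.8)), 3 * se[k + 1])
  expect_lt(abs(fit$kappa - 0.5), 3 * se[k + 2])
})

test_that("likelihoods nest: lognormal <= GG <= GB2(log)", {
  d <- heavy_tail_population(1500, seed = 47, n_morbidity = 4)
  ll_ln <- fit_lognormal(d)$loglik
  gg <- fit_gg(d)
  gb2 <- fit_gb2(d, "log")
  expect_gte(gg$loglik, ll_ln - 1e-3)
  expect_gte(gb2$loglik, gg$loglik - 1e-3)
})

test_that("GB2 ML recovers its own DGP within 3 SEs", {
  X <- tiny_design(5000, seed = 53)
  beta <- c(1.5, 0.3, 0, 0, -0.2, rep(0, ncol(X) - 5))
  d <- simulate_costs(X, dgp_config("gb2", coefficients = beta,
                                    shape = list(a = 2, p = 1.5, q = 2.5),
                                    seed = 54))
  fit <- fit_gb2(d, "log")
  expect_true(fit$converged)
  k <- ncol(X)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta - beta) < 3 * se[1:k]))
  expect_lt(abs(log(fit$a) - log(2)), 3 * se[k + 1])
  expect_lt(abs(log(fit$p) - log(1.5)), 3 * se[k + 2])
  expect_lt(abs(log(fit$q) - log(2.5)), 3 * se[k + 3])
})
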