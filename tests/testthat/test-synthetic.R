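test_that("covariate design has the documented layout and is reproducible", {
  spec <- covariate_spec(n = 10, n_morbidity = 0)
  X <- make_covariates(spec, seed = 1)
  expect_equal(dim(X), c(10L, 8L))
  expect_identical(X, make_covariates(spec, seed = 1))
  expect_false(identical(X, make_covariates(spec, seed = 2)))
  expect_true(all(X[, "intercept"] == 1))
  expect_equal(X[, "age2"], X[, "age"]^2, ignore_attr = TRUE)
  expect_equal(X[, "fem_age"], X[, "female"] * X[, "age"], ignore_attr = TRUE)

  X24 <- make_covariates(covariate_spec(n = 10000, n_morbidity = 24), seed = 3)
  expect_equal(ncol(X24), 32L)
  spec24 <- covariate_spec(n = 10000, n_morbidity = 24)
  for (j in seq_len(24)) {
    p <- spec24$morbidity_prevalences[j]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(X24[, 8 + j]) - p), 3 * se + 1e-12)
  }
  expect_error(covariate_spec(n = 0), "positive")
})

test_that("design is full column rank at moderate n", {
  X <- make_covariates(covariate_spec(n = 2000, n_morbidity = 24), seed = 5)
  expect_equal(qr(X)$rank, ncol(X))
})

test_that("simulated outcomes match the closed-form family means", {
  n <- 50000
  X <- matrix(1, n, 1)
  # gamma, log link, intercept-only: mean = alpha * exp(c)
  d <- simulate_costs(X, dgp_config("gamma_glm", link = "log",
                                    coefficients = 1.3,
                                    shape = list(alpha = 2), seed = 9))
  mu <- 2 * exp(1.3)
  se <- sqrt(mu^2 / 2 / n)  # var = alpha * scale^2
  expect_lt(abs(mean(d$y) - mu), 3 * se)
  expect_true(all(d$y > 0))

  # lognormal with sigma^2 = 2 ln 2 and zero index: mean -> 2
  d <- simulate_costs(X, dgp_config("lognormal", coefficients = 0,
                                    shape = list(sigma = sqrt(2 * log(2))),
                                    seed = 10))
  v <- (exp(2 * log(2)) - 1) * 4
  expect_lt(abs(mean(d$y) - 2), 3 * sqrt(v / n))

  # generalized gamma: mean formula
  pars <- list(beta = 0.7, sigma = 0.8, kappa = 0.5)
  d <- simulate_costs(X, dgp_config("generalized_gamma",
                                    coefficients = pars$beta,
                                    shape = list(sigma = 0.8, kappa = 0.5),
                                    seed = 11))
  m_th <- mean_gg(pars, matrix(1, 1, 1))
  expect_lt(abs(mean(d$y) - m_th), 3 * stats::sd(d$y) / sqrt(n))

  # gb2: mean formula
  gp <- list(a = 2, p = 1.5, q = 2.5, link = "log", beta = 0.4)
  d <- simulate_costs(X, dgp_config("gb2", coefficients = 0.4,
                                    shape = list(a = 2, p = 1.5, q = 2.5),
                                    seed = 12))
  m_th <- mean_gb2(gp, matrix(1, 1, 1))
  expect_lt(abs(mean(d$y) - m_th), 3 * stats::sd(d$y) / sqrt(n))

  # gamma mixture, log link: Eq-12-style mean
  B <- cbind(c(0.5), c(2))
  d <- simulate_costs(X, dgp_config("gamma_mixture", link = "log",
                                    coefficients = B,
                                    shape = list(pi = c(0.7, 0.3),
                                                 alpha = c(1, 2)), seed = 13))
  m_th <- 0.7 * 1 * exp(0.5) + 0.3 * 2 * exp(2)
  expect_lt(abs(mean(d$y) - m_th), 3 * stats::sd(d$y) / sqrt(n))
})

test_that("same dgp seed is bit-identical; sqrt index validated", {
  X <- tiny_design(200, seed = 2)
  cfg <- dgp_config("gamma_glm", link = "log",
                    coefficients = c(2, rep(0, ncol(X) - 1)),
                    shape = list(alpha = 1.5), seed = 7)
  expect_identical(simulate_costs(X, cfg)$y, simulate_costs(X, cfg)$y)
  bad <- dgp_config("gamma_glm", link = "sqrt",
                    coefficients = c(-5, rep(0, ncol(X) - 1)),
                    shape = list(alpha = 1), seed = 7)
  expect_error(simulate_costs(X, bad), "non-positive")
  expect_error(dgp_config("gamma_glm", coefficients = 1,
                          shape = list(alpha = -1)), "positive")
  expect_error(dgp_config("gb2", coefficients = 1,
                          shape = list(a = 2, p = 1, q = 0.3)), "q > 1/a")
})

test_that("rounding to a tariff grid creates mass points", {
  X <- matrix(1, 500, 1)
  cfg <- dgp_config("lognormal", coefficients = 7, shape = list(sigma = 1),
                    seed = 3, round_to = 50)
  y <- simulate_costs(X, cfg)$y
  expect_true(all(y %% 50 == 0))
  expect_true(all(y > 0))
  expect_lt(length(unique(y)), 300)
})

test_that("heavy-tail population mirrors skewed cost data", {
  d <- heavy_tail_population(200000, seed = 21)
  y <- d$y
  skew <- mean((y - mean(y))^3) / stats::sd(y)^3
  expect_gt(skew, 10)
  expect_gt(mean(y) / stats::median(y), 2)
  expect_lt(mean(y) / stats::median(y), 2.8)
  # conditional variance rises with the conditional mean (quantiles of the
  # generating index)
  eta <- drop(d$X %*% heavy_tail_dgp()$coefficients)
  qs <- cut(eta, stats::quantile(eta, seq(0, 1, 0.1)), include.lowest = TRUE)
  mns <- tapply(y, qs, mean)
  vrs <- tapply(y, qs, stats::var)
  expect_gt(stats::cor(mns, vrs, method = "spearman"), 0.8)
})

test_that("population split is an exact partition with balanced halves", {
  d <- heavy_tail_population(101, seed = 4, n_morbidity = 2)
  sp <- split_population(d, seed = 8)
  expect_setequal(c(sp$estimation$y, sp$validation$y), d$y)
  expect_equal(sort(c(length(sp$estimation$y), length(sp$validation$y))),
               c(50L, 51L))
  d2 <- heavy_tail_population(100, seed = 4, n_morbidity = 2)
  sp2 <- split_population(d2, seed = 8)
  expect_equal(length(sp2$estimation$y), 50L)
  expect_equal(length(intersect(rownames(sp2$estimation$X),
                                rownames(sp2$validation$X))), 0L)

  # halves of a large population agree to sampling error
  big <- heavy_tail_population(60000, seed = 5)
  spb <- split_population(big, seed = 6)
  m1 <- mean(spb$estimation$y); m2 <- mean(spb$validation$y)
  pooled_se <- stats::sd(big$y) * sqrt(2 / 30000)
  expect_lt(abs(m1 - m2), 4 * pooled_se)
  expect_lt(abs(stats::median(spb$estimation$y) /
                  stats::median(spb$validation$y) - 1), 0.05)
})

test_that("cost datasets round-trip through CSV", {
  d <- heavy_tail_population(50, seed = 31, n_morbidity = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_csv(d, path)
  d2 <- read_cost_csv(path)
  expect_equal(d2$y, d$y)
  expect_equal(unname(d2$X), unname(d$X), ignore_attr = TRUE)
})
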