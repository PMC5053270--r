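# Shared fixture builders. All data are generated in code under fixed seeds.

# Small design: intercept + age terms + gender + interactions + m markers.
tiny_design <- function(n, m = 2L, seed = 1L) {
  make_covariates(covariate_spec(n = n, n_morbidity = m), seed = seed)
}

# Gamma-GLM dataset with log link: mean = alpha * exp(X beta).
gamma_log_data <- function(n, beta, alpha = 2, seed = 1L, m = 2L) {
  X <- tiny_design(n, m = m, seed = seed)
  beta <- c(beta, rep(0, ncol(X) - length(beta)))
  simulate_costs(X, dgp_config("gamma_glm", link = "log", coefficients = beta,
                               shape = list(alpha = alpha), seed = seed + 1L))
}

# Gamma dataset with sqrt link: mean = alpha * (X beta)^2, index positive.
# The index spans a wide mean range (like real cost data), which is also
# what makes the Box-Cox link parameter well identified.
gamma_sqrt_data <- function(n, alpha = 2, seed = 1L, m = 2L) {
  X <- tiny_design(n, m = m, seed = seed)
  beta <- c(30, 8, 0, 0, 3, 0, 0, 0, rep(4, ncol(X) - 8L))
  simulate_costs(X, dgp_config("gamma_glm", link = "sqrt", coefficients = beta,
                               shape = list(alpha = alpha), seed = seed + 1L))
}

# Homoscedastic lognormal dataset.
lognormal_data <- function(n, beta, sigma = 1, seed = 1L, m = 2L) {
  X <- tiny_design(n, m = m, seed = seed)
  beta <- c(beta, rep(0, ncol(X) - length(beta)))
  simulate_costs(X, dgp_config("lognormal", coefficients = beta,
                               shape = list(sigma = sigma), seed = seed + 1L))
}

# Numerical quadrature of f (vectorized density) over (0, Inf).
quad01 <- function(f, ...) {
  stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12, ...)$value
}
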