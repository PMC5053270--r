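# Quasi-likelihood GLMs: log or sqrt link crossed with variance mu (Poisson
# type) or mu^2 (gamma type). Estimation is IRLS via stats::glm.fit with a
# quasi() family; the sqrt link starts from OLS on sqrt(y) and restricts the
# linear index to stay positive (the squared link is sign-symmetric, so the
# positive branch is an identifiability constraint, enforced by glm.fit's
# step-halving against valideta).

sqrt_link_positive <- function() {
  lk <- stats::make.link("sqrt")
  lk$valideta <- function(eta) all(is.finite(eta)) && all(eta > 0)
  lk
}

# quasi() captures its variance argument unevaluated, so select the family
# with literal arguments.
quasi_family <- function(link, var_power) {
  lnk <- if (link == "log") "log" else sqrt_link_positive()
  if (var_power == 1) stats::quasi(link = lnk, variance = "mu")
  else stats::quasi(link = lnk, variance = "mu^2")
}

#' Fit a quasi-likelihood GLM for costs
#'
#' Solves the quasi-score equations
#' `sum_i (dmu_i/dbeta) (y_i - mu_i) / V(mu_i) = 0` with `mu = g^-1(X beta)`
#' and `V(mu) = mu^var_power`. The dispersion is estimated from Pearson
#' residuals.
#'
#' @param data A [cost_dataset()].
#' @param link `"log"` or `"sqrt"`.
#' @param var_power 1 (variance proportional to the mean, Poisson type) or 2
#'   (variance proportional to the squared mean, gamma type).
#' @return An object of class `glm_quasi_fit` with `beta`, `dispersion`,
#'   `converged`, `iterations`, `link`, `var_power` and in-sample
#'   `fitted_means`.
#' @export
fit_glm <- function(data, link = c("log", "sqrt"), var_power = 1) {
  stopifnot(inherits(data, "cost_dataset"))
  link <- match.arg(link)
  if (!var_power %in% c(1, 2)) stop("var_power must be 1 or 2", call. = FALSE)
  X <- data$X
  y <- data$y
  fam <- quasi_family(link, var_power)
  start <- if (link == "log") {
    stats::lm.fit(X, log(y))$coefficients
  } else {
    stats::lm.fit(X, sqrt(y))$coefficients
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, start = start,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  mu <- fit$fitted.values
  pearson <- sum((y - mu)^2 / mu^var_power) / (length(y) - fit$rank)
  structure(
    list(link = link, var_power = var_power, beta = fit$coefficients,
         dispersion = pearson, converged = fit$converged,
         iterations = fit$iter, fitted_means = mu,
         column_names = colnames(X)),
    class = "glm_quasi_fit"
  )
}

#' Conditional-mean predictions from a quasi-GLM
#'
#' @param fit A [fit_glm()] object.
#' @param X_new Design matrix.
#' @return `exp(X beta)` for the log link, `(X beta)^2` for the sqrt link.
#' @export
predict_mean <- function(fit, X_new) {
  stopifnot(inherits(fit, "glm_quasi_fit"))
  eta <- drop(as.matrix(X_new) %*% fit$beta)
  if (fit$link == "log") exp(eta) else eta^2
}
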