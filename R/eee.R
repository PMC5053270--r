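# Extended estimating equations: a GLM generalization in which the link is a
# Box-Cox function with estimated parameter lambda (lambda = 0 log link,
# lambda = 0.5 square-root link) and the variance is a power function of the
# mean, var(y|X) = theta1 * mu^theta2, with theta1 and theta2 estimated.
#
# The estimating-equation system treats lambda as a mean parameter: (beta,
# lambda) jointly satisfy the quasi-score sum_i D_i' (y_i - mu_i)/V_i = 0,
# which is unbiased whenever the regressor specification is correct,
# irrespective of higher moments. It is solved block-wise: beta by IRLS at
# fixed lambda, lambda by 1-d root finding on its profiled score component;
# theta2 is updated from a Park-type gamma regression of squared residuals
# on log mu and theta1 from the Pearson moment, alternating to convergence.

#' Box-Cox mean link
#'
#' `mu = (lambda * index + 1)^(1/lambda)`, with the continuous limit
#' `exp(index)` at `lambda = 0`. Requires `lambda * index + 1 > 0`.
#'
#' @param lam Box-Cox parameter.
#' @param index Linear index values.
#' @return Conditional means.
#' @export
eee_link <- function(lam, index) {
  if (abs(lam) < 1e-7) return(exp(index))
  z <- lam * index + 1
  if (any(z <= 0)) {
    bad <- which(z <= 0)
    stop(sprintf("Box-Cox link domain violated (lambda*index + 1 <= 0) for %d row(s), first at row %d",
                 length(bad), bad[1]), call. = FALSE)
  }
  z^(1 / lam)
}

# Inverse of the Box-Cox mean link: index = (mu^lambda - 1)/lambda.
eee_linkfun <- function(lam, mu) {
  if (abs(lam) < 1e-7) log(mu) else (mu^lam - 1) / lam
}

# mu, dmu/deta and dmu/dlambda for the Box-Cox mean; requires
# lambda*eta + 1 > 0 away from the log limit.
eee_mean_parts <- function(lam, eta) {
  if (abs(lam) < 1e-5) {
    mu <- exp(eta)
    return(list(mu = mu, dmu_deta = mu, dmu_dlam = mu * (-eta^2 / 2)))
  }
  z <- lam * eta + 1
  mu <- z^(1 / lam)
  dlogmu_dlam <- (eta / z) / lam - log(z) / lam^2
  list(mu = mu, dmu_deta = z^(1 / lam - 1), dmu_dlam = mu * dlogmu_dlam)
}

# IRLS for beta at fixed (lambda, theta2); step-halves to stay inside the
# Box-Cox domain. Returns NULL when no admissible step exists.
eee_irls <- function(X, y, lam, theta2, beta0 = NULL, maxit = 60, tol = 1e-10) {
  if (is.null(beta0)) {
    beta0 <- stats::lm.fit(X, eee_linkfun(lam, y))$coefficients
  }
  admissible <- function(eta) {
    abs(lam) < 1e-5 || all(lam * eta + 1 > 0)
  }
  beta <- beta0
  eta <- drop(X %*% beta)
  if (!admissible(eta)) {
    # pull the start towards a flat index until admissible
    for (sh in 2^-(1:30)) {
      beta_try <- beta0 * sh
      beta_try[1] <- beta0[1] * sh + eee_linkfun(lam, mean(y)) * (1 - sh)
      eta <- drop(X %*% beta_try)
      if (admissible(eta)) { beta <- beta_try; break }
    }
    if (!admissible(eta)) return(NULL)
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mp <- eee_mean_parts(lam, eta)
    w <- mp$dmu_deta^2 / mp$mu^theta2
    z <- eta + (y - mp$mu) / mp$dmu_deta
    beta_new <- stats::lm.wfit(X, z, w)$coefficients
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_c <- drop(X %*% cand)
      if (admissible(eta_c)) break
      step <- step / 2
      if (step < 1e-10) return(list(beta = beta, mu = mp$mu, converged = FALSE))
    }
    move <- sum(abs(step * (beta_new - beta))) / (1 + sum(abs(beta)))
    beta <- cand
    eta <- eta_c
    if (move < tol) { converged <- TRUE; break }
  }
  list(beta = beta, mu = eee_mean_parts(lam, eta)$mu, converged = converged)
}

# Profiled lambda score: quasi-score component for lambda with beta solved
# by IRLS at each lambda. Root of this function (in lambda) solves the joint
# mean-parameter estimating equations.
eee_lambda_score <- function(lam, X, y, theta2, beta0 = NULL) {
  ir <- eee_irls(X, y, lam, theta2, beta0 = beta0)
  if (is.null(ir) || !ir$converged) return(NA_real_)
  eta <- drop(X %*% ir$beta)
  mp <- eee_mean_parts(lam, eta)
  list(score = sum(mp$dmu_dlam * (y - mp$mu) / mp$mu^theta2), beta = ir$beta)
}

# Park-type regression for the variance power: gamma GLM of squared
# residuals on log(mu); the slope estimates theta2.
park_theta2 <- function(y, mu) {
  r2 <- (y - mu)^2
  Z <- cbind(1, log(mu))
  fit <- try(suppressWarnings(
    stats::glm.fit(Z, r2, family = quasi_family("log", 2),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged) return(NA_real_)
  unname(fit$coefficients[2])
}

#' Fit the extended estimating equations model
#'
#' @param data A [cost_dataset()].
#' @param lam Optional fixed Box-Cox parameter; when supplied together with
#'   `theta2`, only the index coefficients (and theta1) are estimated, which
#'   reproduces the corresponding quasi-GLM mean fit.
#' @param theta2 Optional fixed variance power.
#' @param lam_range Interval searched for the link parameter.
#' @param max_outer Maximum alternations between the mean block (beta,
#'   lambda) and the variance block (theta1, theta2).
#' @return List of class `eee_fit` with `beta`, `lam`, `theta1`, `theta2`,
#'   `converged` and in-sample `fitted_means`.
#' @export
fit_eee <- function(data, lam = NULL, theta2 = NULL, lam_range = c(-0.5, 1.5),
                    max_outer = 20L) {
  stopifnot(inherits(data, "cost_dataset"))
  X <- data$X
  y <- data$y
  if (!is.null(lam) && !is.null(theta2)) {
    ir <- eee_irls(X, y, lam, theta2)
    if (is.null(ir)) {
      return(structure(list(beta = NULL, lam = lam, theta1 = NA,
                            theta2 = theta2, converged = FALSE,
                            fitted_means = NULL, column_names = colnames(X)),
                       class = "eee_fit"))
    }
    th1 <- mean((y - ir$mu)^2 / ir$mu^theta2)
    return(structure(
      list(beta = ir$beta, lam = lam, theta1 = th1, theta2 = theta2,
           converged = ir$converged, fitted_means = ir$mu,
           column_names = colnames(X)),
      class = "eee_fit"))
  }
  solve_lambda <- function(t2, beta0) {
    grid <- seq(lam_range[1], lam_range[2], length.out = 9)
    sc <- vapply(grid, function(l) {
      s <- eee_lambda_score(l, X, y, t2, beta0)
      if (is.list(s)) s$score else NA_real_
    }, numeric(1))
    ok <- which(is.finite(sc))
    if (length(ok) < 2) return(NULL)
    sgn <- sign(sc[ok])
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flip) == 0) return(NULL)
    # bracket closest to the previous interior solution
    i <- ok[flip[1]]; j <- ok[flip[1] + 1]
    root <- stats::uniroot(function(l) {
      s <- eee_lambda_score(l, X, y, t2, beta0)
      if (is.list(s)) s$score else NA_real_
    }, c(grid[i], grid[j]), tol = 1e-7)
    root$root
  }
  l <- NA
  t2 <- 2
  beta0 <- NULL
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    l_new <- tryCatch(solve_lambda(t2, beta0), error = function(e) NULL)
    if (is.null(l_new)) { l <- NA; break }
    s <- eee_lambda_score(l_new, X, y, t2, beta0)
    if (!is.list(s)) { l <- NA; break }
    beta0 <- s$beta
    ir <- eee_irls(X, y, l_new, t2, beta0 = beta0)
    t2_new <- park_theta2(y, ir$mu)
    if (!is.finite(t2_new)) { l <- NA; break }
    t2_new <- min(max(t2_new, -2), 6)
    done <- is.finite(l) && abs(l_new - l) < 1e-5 && abs(t2_new - t2) < 1e-4
    l <- l_new
    t2 <- t2_new
    if (done) { converged <- TRUE; break }
  }
  if (!is.finite(l)) {
    return(structure(list(beta = NULL, lam = NA, theta1 = NA, theta2 = NA,
                          converged = FALSE, fitted_means = NULL,
                          column_names = colnames(X)),
                     class = "eee_fit"))
  }
  ir <- eee_irls(X, y, l, t2, beta0 = beta0)
  th1 <- mean((y - ir$mu)^2 / ir$mu^t2)
  structure(
    list(beta = ir$beta, lam = l, theta1 = th1, theta2 = t2,
         converged = converged && ir$converged, fitted_means = ir$mu,
         column_names = colnames(X)),
    class = "eee_fit"
  )
}

#' Conditional-mean predictions from an EEE fit
#'
#' @param fit A [fit_eee()] object.
#' @param X_new Design matrix.
#' @return `(lambda X beta + 1)^(1/lambda)` (log limit at lambda = 0).
#' @export
predict_eee <- function(fit, X_new) {
  stopifnot(inherits(fit, "eee_fit"))
  eee_link(fit$lam, drop(as.matrix(X_new) %*% fit$beta))
}
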