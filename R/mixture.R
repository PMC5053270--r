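# Two-component finite mixtures of gamma densities. Component j is a gamma
# with shape alpha_j and scale s_j(X), where s_j(X) = exp(X beta_j) under the
# log link and (X beta_j)^2 under the square-root link, so the component mean
# is alpha_j * s_j(X) and the mixture mean is sum_j pi_j alpha_j s_j(X).
# Class-membership probabilities pi_j are constant across individuals.
#
# Estimation is EM with weighted gamma-GLM M-steps (the gamma quasi-score for
# the mean index does not involve the shape) and an exact weighted MLE update
# for each shape via the digamma equation. Multiple starts guard against
# multimodality: a k-means-on-log(y) start plus random responsibility starts
# drawn from an internal deterministic generator.

# Per-component log-density matrix (n x C) given scale matrix S.
fmm_logdens <- function(y, alpha, S) {
  C <- length(alpha)
  vapply(seq_len(C), function(j) {
    stats::dgamma(y, shape = alpha[j], scale = S[, j], log = TRUE)
  }, numeric(length(y)))
}

#' Gamma-mixture log-likelihood
#'
#' @param params List with `pi` (mixing probabilities), `alpha` (component
#'   shapes), `betas` (k x C matrix of per-component index coefficients) and
#'   `link` (`"log"` or `"sqrt"`).
#' @param data A [cost_dataset()].
#' @return `sum_i log sum_j pi_j f_j(y_i | X_i)` computed by log-sum-exp.
#' @export
fmm_loglik <- function(params, data) {
  stopifnot(inherits(data, "cost_dataset"))
  S <- apply(as.matrix(params$betas), 2L,
             function(b) link_scale(drop(data$X %*% b), params$link))
  ld <- fmm_logdens(data$y, params$alpha, S)
  sum(row_logsumexp(sweep(ld, 2L, log(params$pi), "+")))
}

#' Gamma-mixture conditional mean
#'
#' `E[y|X] = sum_j pi_j alpha_j exp(X beta_j)` (log link) or
#' `sum_j pi_j alpha_j (X beta_j)^2` (sqrt link).
#'
#' @inheritParams fmm_loglik
#' @param X_new Design matrix.
#' @return Vector of conditional means.
#' @export
fmm_mean <- function(params, X_new) {
  X_new <- as.matrix(X_new)
  B <- as.matrix(params$betas)
  means <- vapply(seq_along(params$pi), function(j) {
    eta <- drop(X_new %*% B[, j])
    s <- if (params$link == "log") exp(eta) else eta^2
    params$alpha[j] * s
  }, numeric(nrow(X_new)))
  drop(means %*% params$pi)
}

# Weighted gamma shape MLE: solves digamma(a) - log(a) = rhs, rhs < 0.
solve_gamma_shape <- function(rhs) {
  if (rhs >= 0) return(1e6)
  f <- function(la) digamma(exp(la)) - la - rhs
  # digamma(a) - log(a) is increasing in a, -> 0- as a -> Inf
  lo <- -10; hi <- 15
  if (f(hi) < 0) return(exp(hi))
  if (f(lo) > 0) return(exp(lo))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

# One EM run from given responsibilities; maxit caps EM sweeps.
fmm_em_run <- function(X, y, link, resp, maxit, tol = 1e-8) {
  n <- length(y)
  C <- ncol(resp)
  k <- ncol(X)
  fam <- quasi_family(link, 2)
  beta_mean <- matrix(NA_real_, k, C)  # mean-parameterized index
  start0 <- if (link == "log") stats::lm.fit(X, log(y))$coefficients else
    stats::lm.fit(X, sqrt(y))$coefficients
  alpha <- rep(1, C)
  pi_j <- colMeans(resp)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    # M-step: weighted gamma GLM per component for the mean, then shape MLE
    for (j in seq_len(C)) {
      w <- pmax(resp[, j], 1e-10)
      st <- if (anyNA(beta_mean[, j])) start0 else beta_mean[, j]
      g <- try(suppressWarnings(
        stats::glm.fit(X, y, weights = w, family = fam, start = st,
                       control = stats::glm.control(epsilon = 1e-9, maxit = 10))
      ), silent = TRUE)
      if (inherits(g, "try-error")) return(NULL)
      beta_mean[, j] <- g$coefficients
      mu <- g$fitted.values
      rhs <- 1 + sum(w * (log(y / mu) - y / mu)) / sum(w)
      alpha[j] <- solve_gamma_shape(rhs)
    }
    pi_j <- colMeans(resp)
    # E-step quantities and observed-data loglik
    S <- vapply(seq_len(C), function(j) {
      eta <- drop(X %*% beta_mean[, j])
      mu <- if (link == "log") exp(eta) else eta^2
      mu / alpha[j]
    }, numeric(n))
    if (any(!is.finite(S)) || any(S <= 0)) return(NULL)
    ld <- fmm_logdens(y, alpha, S) + rep(log(pmax(pi_j, 1e-300)), each = n)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    resp <- exp(ld - lse)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <
        tol * (1 + abs(ll_trace[it - 1]))) {
      converged <- TRUE
      break
    }
  }
  list(pi = pi_j, alpha = alpha, beta_mean = beta_mean, loglik = ll,
       ll_trace = ll_trace, resp = resp, converged = converged)
}

#' Fit a two-component gamma mixture
#'
#' EM estimation with multiple starts: one k-means partition of `log(y)` and
#' `n_random` random-responsibility starts (drawn from a deterministic
#' internal stream seeded by `seed`, so fits are reproducible and do not
#' disturb the session RNG). Each start is run for a short burn-in and the
#' best is run to convergence. Components are reported in increasing order of
#' their average fitted mean, which makes the output invariant to label
#' switching.
#'
#' @param data A [cost_dataset()].
#' @param link `"log"` or `"sqrt"`.
#' @param C Number of components (2, the supported default).
#' @param n_random Number of random starts besides the k-means start.
#' @param seed Seed for the internal start generator.
#' @param maxit Maximum EM sweeps for the final run.
#' @return List of class `fmm_fit` with `pi`, `alpha`, `betas`
#'   (scale-parameterized, as used by [fmm_mean()]), `link`, `loglik`,
#'   `ll_trace`, `converged`.
#' @export
fit_fmm <- function(data, link = c("log", "sqrt"), C = 2L, n_random = 5L,
                    seed = 1L, maxit = 400L) {
  stopifnot(inherits(data, "cost_dataset"))
  link <- match.arg(link)
  X <- data$X
  y <- data$y
  n <- length(y)
  starts <- list()
  km <- stats::kmeans(log(y), centers = C, nstart = 1,
                      iter.max = 25)
  resp_km <- matrix(0.05 / (C - 1), n, C)
  resp_km[cbind(seq_len(n), km$cluster)] <- 0.95
  starts[[1]] <- resp_km
  for (r in seq_len(n_random)) {
    u <- matrix(lcg_runif(n * C, seed * 1000 + r), n, C) + 0.2
    starts[[r + 1]] <- u / rowSums(u)
  }
  burn <- lapply(starts, function(r0) fmm_em_run(X, y, link, r0, maxit = 15L))
  ok <- !vapply(burn, is.null, logical(1))
  if (!any(ok)) {
    return(structure(list(pi = NULL, alpha = NULL, betas = NULL, link = link,
                          loglik = -Inf, converged = FALSE),
                     class = "fmm_fit"))
  }
  lls <- vapply(burn, function(b) if (is.null(b)) -Inf else b$loglik, numeric(1))
  run <- fmm_em_run(X, y, link, burn[[which.max(lls)]]$resp, maxit = maxit)
  if (is.null(run)) {
    return(structure(list(pi = NULL, alpha = NULL, betas = NULL, link = link,
                          loglik = -Inf, converged = FALSE),
                     class = "fmm_fit"))
  }
  degenerate <- any(run$pi < 1e-4) || any(run$alpha >= 1e6)
  # convert mean-parameterized indices to scale-parameterized (Eq. 12/13 form)
  betas <- run$beta_mean
  for (j in seq_len(C)) {
    if (link == "log") betas[1, j] <- betas[1, j] - log(run$alpha[j])
    else betas[, j] <- betas[, j] / sqrt(run$alpha[j])
  }
  # canonical order: ascending average fitted component mean
  cm <- vapply(seq_len(C), function(j) {
    eta <- drop(X %*% run$beta_mean[, j])
    mean(if (link == "log") exp(eta) else eta^2)
  }, numeric(1))
  ord <- order(cm)
  structure(
    list(pi = run$pi[ord], alpha = run$alpha[ord],
         betas = betas[, ord, drop = FALSE], link = link,
         loglik = run$loglik, ll_trace = run$ll_trace,
         converged = run$converged && !degenerate,
         column_names = colnames(X)),
    class = "fmm_fit"
  )
}
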