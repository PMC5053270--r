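# Conditional density approximation estimator: the cost range is divided
# into Q intervals (equal-probability/quantile intervals; with skewness
# above 10, equal-width intervals would leave almost every upper bin empty
# and the interval logits unestimable). Interval membership is modelled by a
# multinomial logit (one coefficient vector per interval, first normalized
# to zero) or an ordered logit (one coefficient vector plus Q-1 increasing
# thresholds). The conditional mean is the probability-weighted sum of the
# estimation-sample bin means, which do not vary with covariates.

#' Partition the observed cost range into quantile intervals
#'
#' Boundaries are the empirical quantiles of `y`, so the lowest boundary is
#' the minimum observed cost and the highest the maximum. Mass points that
#' collapse adjacent quantiles are merged with a warning. Observations are
#' assigned left-closed/right-open, with the last interval closed (a value
#' equal to an interior boundary belongs to the interval that starts there).
#'
#' @param y Strictly positive cost vector.
#' @param Q Number of intervals (default 15).
#' @return Object of class `interval_partition` with `Q` (surviving interval
#'   count), `boundaries` (length `Q + 1`), `bin_means` and `bin_counts`.
#' @export
build_partition <- function(y, Q = 15L) {
  if (Q < 2L) stop("Q must be at least 2", call. = FALSE)
  if (length(unique(y)) < Q) {
    stop("too few distinct cost values for the requested number of intervals",
         call. = FALSE)
  }
  bounds <- unname(stats::quantile(y, probs = seq(0, 1, length.out = Q + 1),
                                   type = 7))
  ub <- unique(bounds)
  if (length(ub) < length(bounds)) {
    warning(sprintf(
      "mass points collapsed %d interval(s); %d intervals retained",
      length(bounds) - length(ub), length(ub) - 1L), call. = FALSE)
    bounds <- ub
  }
  if (length(bounds) < 3L) {
    stop("fewer than 2 intervals survive after merging mass points",
         call. = FALSE)
  }
  idx <- assign_intervals(y, bounds)
  counts <- tabulate(idx, nbins = length(bounds) - 1L)
  if (any(counts == 0L)) {
    stop("internal error: empty interval in quantile partition", call. = FALSE)
  }
  structure(
    list(Q = length(bounds) - 1L, boundaries = bounds,
         bin_means = as.numeric(tapply(y, idx, mean)), bin_counts = counts),
    class = "interval_partition"
  )
}

# Left-closed/right-open assignment; last interval closed above.
assign_intervals <- function(y, boundaries) {
  idx <- findInterval(y, boundaries, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(boundaries) - 1L] <- length(boundaries) - 1L
  idx
}

#' Fit a conditional density approximation estimator
#'
#' @param data A [cost_dataset()] (the estimation sample; the partition must
#'   have been built on the same sample).
#' @param partition A [build_partition()] object.
#' @param model `"multinomial"` (one logit index per interval) or `"ordered"`
#'   (proportional-odds logit with increasing thresholds).
#' @return Object of class `cde_fit` with `partition`, `model`, `loglik`,
#'   `converged` and the logit coefficients: `mnl_betas` (Q x k, first row
#'   zero) or `ol_psi` / `ol_beta`.
#' @export
fit_cde <- function(data, partition, model = c("multinomial", "ordered")) {
  stopifnot(inherits(data, "cost_dataset"),
            inherits(partition, "interval_partition"))
  model <- match.arg(model)
  X <- data$X
  lab <- factor(assign_intervals(data$y, partition$boundaries),
                levels = seq_len(partition$Q))
  Xn <- X[, -1, drop = FALSE]  # logit fitters add their own intercepts
  df <- data.frame(Xn, check.names = TRUE)
  if (model == "multinomial") {
    fit <- try(nnet::multinom(lab ~ ., data = cbind(lab = lab, df),
                              maxit = 600, trace = FALSE,
                              MaxNWts = 20000, reltol = 1e-12),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(structure(list(partition = partition, model = model,
                            loglik = -Inf, converged = FALSE),
                       class = "cde_fit"))
    }
    co <- stats::coef(fit)  # (Q-1) x k, baseline = interval 1
    B <- rbind(0, as.matrix(co))
    colnames(B)[1] <- "intercept"
    structure(
      list(partition = partition, model = model, mnl_betas = B,
           loglik = -fit$value, converged = fit$convergence == 0,
           column_names = colnames(X)),
      class = "cde_fit")
  } else {
    fit <- try(suppressWarnings(
      MASS::polr(lab ~ ., data = cbind(lab = lab, df), method = "logistic",
                 control = list(maxit = 200))
    ), silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(structure(list(partition = partition, model = model,
                            loglik = -Inf, converged = FALSE),
                       class = "cde_fit"))
    }
    structure(
      list(partition = partition, model = model,
           ol_psi = unname(fit$zeta), ol_beta = unname(stats::coef(fit)),
           loglik = as.numeric(stats::logLik(fit)),
           converged = fit$convergence == 0,
           column_names = colnames(X)),
      class = "cde_fit")
  }
}

#' Interval membership probabilities
#'
#' Multinomial: `p_ij = exp(X_i' b_j) / sum_l exp(X_i' b_l)` with `b_1 = 0`.
#' Ordered: successive differences of the logistic CDF evaluated at
#' `psi_j - X_i' b`, with the last interval absorbing the remainder.
#'
#' @param params A [fit_cde()] object.
#' @param X_new Design matrix (with intercept column, as built by
#'   [make_covariates()]).
#' @return An `n x Q` matrix of probabilities; rows sum to 1.
#' @export
interval_probs <- function(params, X_new) {
  stopifnot(inherits(params, "cde_fit"))
  X_new <- as.matrix(X_new)
  Q <- params$partition$Q
  if (params$model == "multinomial") {
    eta <- X_new %*% t(params$mnl_betas)          # n x Q
    lp <- eta - row_logsumexp(eta)
    P <- exp(lp)
  } else {
    idx <- drop(X_new[, -1, drop = FALSE] %*% params$ol_beta)
    cum <- vapply(params$ol_psi, function(ps) stats::plogis(ps - idx),
                  numeric(nrow(X_new)))
    cum <- cbind(cum, 1)
    P <- cbind(cum[, 1], cum[, -1, drop = FALSE] -
                 cum[, -ncol(cum), drop = FALSE])
  }
  unname(P)
}

#' Convert interval probabilities to discrete hazards
#'
#' `lambda(j) = p_j / (1 - sum_{l<j} p_l)`: the probability of lying in
#' interval j given not lying in any earlier interval. Where the support is
#' exhausted (zero denominator) the hazard is defined as 1.
#'
#' @param probs `n x Q` matrix whose rows sum to 1.
#' @return `n x Q` hazard matrix; the final column is 1 wherever reached.
#' @export
probs_to_hazards <- function(probs) {
  probs <- as.matrix(probs)
  surv <- cbind(1, 1 - t(apply(probs, 1L, cumsum)))[, seq_len(ncol(probs)),
                                                    drop = FALSE]
  H <- probs / surv
  H[surv <= 0] <- 1
  pmin(pmax(H, 0), 1)
}

#' Convert discrete hazards back to interval probabilities
#'
#' Inverse of [probs_to_hazards()]: `p_j = lambda_j prod_{l<j} (1 - lambda_l)`.
#'
#' @param hazards `n x Q` hazard matrix.
#' @return `n x Q` probability matrix.
#' @export
hazards_to_probs <- function(hazards) {
  hazards <- as.matrix(hazards)
  surv <- cbind(1, t(apply(1 - hazards, 1L, cumprod)))[, seq_len(ncol(hazards)),
                                                       drop = FALSE]
  hazards * surv
}

#' Conditional mean from a conditional density estimator
#'
#' `E[y|X] = sum_j p_j(X) ybar_j` with the estimation-sample bin means
#' `ybar_j` held fixed; predictions are therefore bounded by the extreme bin
#' means, a structural difference from the parametric models.
#'
#' @param params A [fit_cde()] object.
#' @param X_new Design matrix.
#' @return Vector of conditional means.
#' @export
cde_mean <- function(params, X_new) {
  drop(interval_probs(params, X_new) %*% params$partition$bin_means)
}
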