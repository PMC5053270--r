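# Forecast-evaluation machinery: MPE / MAPE / RMSE records, the ADMPE
# variability-of-bias measure, the Pearson misspecification test, decile
# profiles of predicted costs, and response surfaces of each metric against
# the inverse sample size.

#' Prediction-error metrics for one model, sample size and replication
#'
#' `MPE = sum(y - yhat)/n` (bias; errors may cancel),
#' `MAPE = sum|y - yhat|/n` (accuracy),
#' `RMSE = sqrt(sum((y - yhat)^2)/n)` (goodness of fit). The divisor is the
#' number of evaluated observations, so each quantity is a mean over the
#' evaluation set.
#'
#' @param y Actual costs.
#' @param yhat Predicted mean costs.
#' @param model Model label.
#' @param Ns Estimation sample size the fit used.
#' @param r Replication id.
#' @return One-row data frame: `model`, `Ns`, `replication`, `mpe`, `mape`,
#'   `rmse`, `n_eval`.
#' @export
compute_metrics <- function(y, yhat, model = "model", Ns = NA_integer_,
                            r = NA_integer_) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 1L) stop("need at least one observation", call. = FALSE)
  e <- y - yhat
  data.frame(model = model, Ns = Ns, replication = r,
             mpe = mean(e), mape = mean(abs(e)), rmse = sqrt(mean(e^2)),
             n_eval = length(y), stringsAsFactors = FALSE)
}

#' Absolute deviation of replication-level bias (ADMPE)
#'
#' For each (model, Ns) cell, adds `admpe = |MPE_r - mean_r(MPE)|`: the
#' absolute deviation of each replication's MPE from the across-replication
#' mean, a variability-of-bias measure. A single replication gives 0.
#'
#' @param records Data frame of [compute_metrics()] rows.
#' @return `records` with an `admpe` column.
#' @export
add_admpe <- function(records) {
  key <- interaction(records$model, records$Ns, drop = TRUE)
  center <- stats::ave(records$mpe, key)
  records$admpe <- abs(records$mpe - center)
  records
}

#' Pearson misspecification test
#'
#' Regresses raw-scale residuals `y - yhat` on the predicted costs (with
#' intercept) and t-tests the slope at the 5% level; a significant slope is
#' evidence of a detectable linear relationship between residuals and
#' predictions, hence of misspecification.
#'
#' @param y Actual costs.
#' @param yhat Predicted mean costs.
#' @return List of class `pearson_test` with `slope`, `p_value`,
#'   `reject_5pct` and `applicable` (`FALSE` when the predictions are
#'   constant, e.g. an intercept-only fit, where the test is undefined).
#' @export
pearson_test <- function(y, yhat) {
  if (length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(yhat) < .Machine$double.eps^0.5 * (1 + abs(mean(yhat)))) {
    return(structure(list(slope = NA_real_, p_value = NA_real_,
                          reject_5pct = NA, applicable = FALSE),
                     class = "pearson_test"))
  }
  fit <- stats::lm((y - yhat) ~ yhat)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["yhat", "Estimate"]
  p <- sm["yhat", "Pr(>|t|)"]
  structure(list(slope = slope, p_value = p, reject_5pct = p < 0.05,
                 applicable = TRUE),
            class = "pearson_test")
}

#' @export
print.pearson_test <- function(x, ...) {
  if (!x$applicable) cat("Pearson test: not applicable (constant predictions)\n")
  else cat(sprintf("Pearson test: slope %.4g, p = %.4g (%s at 5%%)\n",
                   x$slope, x$p_value,
                   if (x$reject_5pct) "rejected" else "not rejected"))
  invisible(x)
}

#' Bias and accuracy by decile of predicted costs
#'
#' Ranks observations by predicted cost (stable order for ties), splits them
#' into ten near-equal groups, and reports per-decile MPE and MAPE.
#'
#' @param y Actual costs.
#' @param yhat Predicted mean costs.
#' @param model Model label carried into the output.
#' @return Data frame with columns `model`, `decile`, `mpe`, `mape`, `n`.
#' @export
decile_profile <- function(y, yhat, model = "model") {
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  ord <- order(yhat)  # stable ties
  dec <- ceiling(seq_len(n) / n * 10)
  out <- lapply(1:10, function(d) {
    i <- ord[dec == d]
    data.frame(model = model, decile = d, mpe = mean(y[i] - yhat[i]),
               mape = mean(abs(y[i] - yhat[i])), n = length(i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Response surface of a metric against inverse sample size
#'
#' Fits `metric_sr = alpha + beta / Ns + u` by OLS across replications and
#' sample sizes for one model. For the strictly positive metrics (MAPE,
#' RMSE, ADMPE) the log of the value is the dependent variable; the MPE is
#' used on its natural scale. The intercept `alpha` estimates the metric's
#' large-sample asymptote; its t-test against 0 indicates whether the
#' estimator is consistent by that metric.
#'
#' @param records Data frame containing `model`, `Ns` and the metric column
#'   (`mpe`, `mape`, `rmse` or `admpe`).
#' @param model Model label to filter on.
#' @param metric One of `"mpe"`, `"mape"`, `"rmse"`, `"admpe"`.
#' @return List of class `response_surface`: `model`, `metric`, `alpha`,
#'   `beta_inv_n`, `alpha_se`, `alpha_p_value`, `log_scale`, `n_points`.
#' @export
fit_response_surface <- function(records, model, metric = c("mpe", "mape",
                                                            "rmse", "admpe")) {
  metric <- match.arg(metric)
  rec <- records[records$model == model, , drop = FALSE]
  if (length(unique(rec$Ns)) < 2L) {
    stop("need at least 2 distinct sample sizes", call. = FALSE)
  }
  v <- rec[[metric]]
  log_scale <- metric != "mpe"
  if (log_scale) {
    if (any(v <= 0)) {
      stop("non-positive metric values under the log specification",
           call. = FALSE)
    }
    v <- log(v)
  }
  inv_n <- 1 / rec$Ns
  fit <- stats::lm(v ~ inv_n)
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(model = model, metric = metric, alpha = sm[1, "Estimate"],
         beta_inv_n = sm[2, "Estimate"], alpha_se = sm[1, "Std. Error"],
         alpha_p_value = sm[1, "Pr(>|t|)"],
         beta_se = sm[2, "Std. Error"], log_scale = log_scale,
         n_points = nrow(rec)),
    class = "response_surface"
  )
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "response surface %s / %s%s: alpha = %.4g (p = %.3g), beta[1/Ns] = %.4g\n",
    x$model, x$metric, if (x$log_scale) " (log)" else "", x$alpha,
    x$alpha_p_value, x$beta_inv_n))
  invisible(x)
}
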