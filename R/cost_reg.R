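#' Model labels available in the comparison
#'
#' The sixteen estimators, by their conventional labels: `OLS` (linear
#' regression on levels), `LOGOLSHET` / `SQRTOLSHET` (transformed linear
#' regression with heteroscedastic smearing), `GLMLOGP`, `GLMLOGG`,
#' `GLMSQRTP`, `GLMSQRTG` (quasi-GLMs, link x variance family), `LOGNORM`,
#' `GG`, `GB2LOG`, `GB2SQRT` (maximum-likelihood parametric families),
#' `FMMLOGG`, `FMMSQRTG` (two-component gamma mixtures), `EEE` (extended
#' estimating equations) and `CDEM`, `CDEO` (conditional density
#' approximation, multinomial and ordered logit).
#'
#' @return Character vector of the sixteen labels.
#' @export
cost_models <- function() {
  c("OLS", "LOGOLSHET", "SQRTOLSHET",
    "GLMLOGP", "GLMLOGG", "GLMSQRTP", "GLMSQRTG",
    "LOGNORM", "GG", "GB2LOG", "GB2SQRT",
    "FMMLOGG", "FMMSQRTG", "EEE", "CDEM", "CDEO")
}

#' Fit one of the sixteen cost regression models
#'
#' Single front end dispatching on the model label. All models share the
#' same covariate vector and expose a conditional-mean predictor on the cost
#' scale via [predict.cost_reg()].
#'
#' @param data A [cost_dataset()], or a formula (with `df` supplied) whose
#'   right-hand side builds the design matrix via [stats::model.matrix()].
#' @param model One of [cost_models()].
#' @param df Data frame, only when `data` is a formula.
#' @param Q Interval count for the conditional density estimators.
#' @param ... Passed to the underlying fitter.
#' @return An object of class `cost_reg` with elements `model`, `fit`,
#'   `converged`, `n` and `fitted` (in-sample mean-cost predictions).
#' @examples
#' pop <- heavy_tail_population(n = 2000, seed = 1, n_morbidity = 4)
#' m <- cost_reg(pop, "GLMSQRTP")
#' m
#' head(predict(m, pop$X))
#' @export
cost_reg <- function(data, model = "OLS", df = NULL, Q = 15L, ...) {
  if (inherits(data, "formula")) {
    if (is.null(df)) stop("supply 'df' with a formula", call. = FALSE)
    mf <- stats::model.frame(data, df)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    colnames(X)[1] <- "intercept"
    data <- cost_dataset(X, stats::model.response(mf))
  }
  stopifnot(inherits(data, "cost_dataset"))
  model <- match.arg(model, cost_models())
  fit <- switch(
    model,
    OLS = fit_transform_ols(data, "identity"),
    LOGOLSHET = fit_transform_ols(data, "log", heteroscedastic = TRUE, ...),
    SQRTOLSHET = fit_transform_ols(data, "sqrt", heteroscedastic = TRUE, ...),
    GLMLOGP = fit_glm(data, "log", 1),
    GLMLOGG = fit_glm(data, "log", 2),
    GLMSQRTP = fit_glm(data, "sqrt", 1),
    GLMSQRTG = fit_glm(data, "sqrt", 2),
    LOGNORM = fit_lognormal(data),
    GG = fit_gg(data, ...),
    GB2LOG = fit_gb2(data, "log", ...),
    GB2SQRT = fit_gb2(data, "sqrt", ...),
    FMMLOGG = fit_fmm(data, "log", ...),
    FMMSQRTG = fit_fmm(data, "sqrt", ...),
    EEE = fit_eee(data, ...),
    CDEM = fit_cde(data, build_partition(data$y, Q), "multinomial"),
    CDEO = fit_cde(data, build_partition(data$y, Q), "ordered")
  )
  conv <- fit$converged %||% TRUE
  obj <- structure(
    list(model = model, fit = fit, converged = conv, n = length(data$y),
         call = match.call()),
    class = "cost_reg"
  )
  obj$fitted <- if (conv) predict(obj, data$X) else NULL
  obj
}

#' Predict mean costs from a fitted model
#'
#' @param object A [cost_reg()] fit.
#' @param newdata Design matrix conformable with the training design.
#' @param ... Unused.
#' @return Vector of conditional-mean predictions on the cost scale.
#' @export
predict.cost_reg <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  f <- object$fit
  switch(
    object$model,
    OLS = , LOGOLSHET = , SQRTOLSHET = retransform_predict(f, X),
    GLMLOGP = , GLMLOGG = , GLMSQRTP = , GLMSQRTG = predict_mean(f, X),
    LOGNORM = mean_lognormal(f, X),
    GG = mean_gg(f, X),
    GB2LOG = , GB2SQRT = mean_gb2(f, X),
    FMMLOGG = , FMMSQRTG = fmm_mean(f, X),
    EEE = predict_eee(f, X),
    CDEM = , CDEO = cde_mean(f, X)
  )
}

#' @export
coef.cost_reg <- function(object, ...) {
  f <- object$fit
  switch(object$model,
         FMMLOGG = , FMMSQRTG = f$betas,
         CDEM = f$mnl_betas,
         CDEO = c(f$ol_psi, f$ol_beta),
         f$beta)
}

#' @export
print.cost_reg <- function(x, ...) {
  cat(sprintf("cost_reg model %s (n = %d, %s)\n", x$model, x$n,
              if (x$converged) "converged" else "NOT converged"))
  f <- x$fit
  extra <- switch(
    x$model,
    LOGNORM = sprintf("sigma = %.4f", f$sigma),
    GG = sprintf("sigma = %.4f, kappa = %.4f", f$sigma, f$kappa),
    GB2LOG = , GB2SQRT = sprintf("a = %.3f, p = %.3f, q = %.3f", f$a, f$p, f$q),
    EEE = sprintf("lambda = %.3f, theta1 = %.3f, theta2 = %.3f",
                  f$lam, f$theta1, f$theta2),
    FMMLOGG = , FMMSQRTG = sprintf("pi = (%s), alpha = (%s)",
                                   paste(round(f$pi, 3), collapse = ", "),
                                   paste(round(f$alpha, 3), collapse = ", ")),
    CDEM = , CDEO = sprintf("%d intervals", f$partition$Q),
    NULL)
  if (!is.null(extra)) cat(" ", extra, "\n")
  invisible(x)
}

#' @export
summary.cost_reg <- function(object, ...) {
  out <- list(model = object$model, n = object$n,
              converged = object$converged,
              coefficients = coef(object),
              fitted_summary = if (!is.null(object$fitted))
                summary(object$fitted))
  class(out) <- "summary.cost_reg"
  out
}

#' @export
print.summary.cost_reg <- function(x, ...) {
  cat(sprintf("Model %s, n = %d, converged: %s\n", x$model, x$n, x$converged))
  if (!is.null(x$fitted_summary)) {
    cat("In-sample mean-cost predictions:\n")
    print(x$fitted_summary)
  }
  invisible(x)
}

#' Residuals on the cost scale
#'
#' @param object A [cost_reg()] fit.
#' @param data The [cost_dataset()] to evaluate on (defaults require passing
#'   explicitly; the fit does not retain the outcome).
#' @param ... Unused.
#' @return `y - E^[y|X]` on the cost scale.
#' @export
residuals.cost_reg <- function(object, data, ...) {
  stopifnot(inherits(data, "cost_dataset"))
  data$y - predict(object, data$X)
}

#' Serialize a fitted model to JSON
#'
#' Writes the model label and its parameter vectors (coefficients, shape and
#' smearing parameters where present) as JSON.
#'
#' @param object A [cost_reg()] fit.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "cost_reg"))
  f <- object$fit
  keep <- intersect(names(f),
                    c("transform", "beta", "smearing_model", "link",
                      "var_power", "dispersion", "sigma", "kappa", "a", "p",
                      "q", "pi", "alpha", "betas", "lam", "theta1", "theta2",
                      "mnl_betas", "ol_psi", "ol_beta", "loglik", "converged"))
  payload <- c(list(model = object$model, n = object$n), f[keep])
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Log-likelihood of fully parametric fits
#'
#' @param object A [cost_reg()] fit of a likelihood-based model (`LOGNORM`,
#'   `GG`, `GB2LOG`, `GB2SQRT`, `FMMLOGG`, `FMMSQRTG`, `CDEM`, `CDEO`).
#' @param ... Unused.
#' @return An object of class `logLik`.
#' @export
logLik.cost_reg <- function(object, ...) {
  ll <- object$fit$loglik
  if (is.null(ll)) stop("model has no likelihood", call. = FALSE)
  structure(ll, class = "logLik", nobs = object$n)
}
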