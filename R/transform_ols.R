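#' Linear regression on (transformed) costs with smearing retransformation
#'
#' Fits ordinary least squares on the level, log or square root of cost. For
#' the transformed variants, predictions on the cost scale use a Duan-type
#' smearing correction that may vary with covariates: the residuals of the
#' primary regression are passed through the inverse transformation
#' (`exp(residual)` for log, `residual^2` for sqrt) and regressed on the same
#' covariates; the fitted values of this auxiliary regression are each
#' observation's smearing factor.
#'
#' The smearing enters multiplicatively under the log transform
#' (`E[y|X] = exp(X'b) E[e^eps|X]`) and additively under the square-root
#' transform (`E[y|X] = (X'b)^2 + E[eps^2|X]`); the placement is forced by
#' the conditional-mean algebra of each transform.
#'
#' @param data A [cost_dataset()].
#' @param transform One of `"identity"`, `"log"`, `"sqrt"`.
#' @param heteroscedastic If `TRUE` (default) the smearing factor is the
#'   fitted value of the auxiliary regression on covariates; if `FALSE` a
#'   constant smearing factor (the sample mean of the transformed residuals)
#'   is used, appropriate only under homoscedasticity.
#' @return An object of class `transform_ols_fit` with elements `transform`,
#'   `beta`, `residuals` (transformed scale), `smearing_model` (auxiliary
#'   coefficients) and `heteroscedastic`.
#' @export
fit_transform_ols <- function(data, transform = c("identity", "log", "sqrt"),
                              heteroscedastic = TRUE) {
  stopifnot(inherits(data, "cost_dataset"))
  transform <- match.arg(transform)
  X <- data$X
  z <- switch(transform, identity = data$y, log = log(data$y),
              sqrt = sqrt(data$y))
  fit <- stats::lm.fit(X, z)
  if (fit$rank < ncol(X)) {
    stop(sprintf("design matrix is rank-deficient (rank %d < %d columns)",
                 fit$rank, ncol(X)), call. = FALSE)
  }
  res <- fit$residuals
  smear <- NULL
  if (transform != "identity") {
    t_res <- if (transform == "log") exp(res) else res^2
    if (heteroscedastic) {
      aux <- stats::lm.fit(X, t_res)
      smear <- aux$coefficients
    } else {
      smear <- c(mean(t_res), rep(0, ncol(X) - 1L))
      names(smear) <- colnames(X)
    }
    if (any(!is.finite(smear))) {
      stop("smearing regression produced non-finite coefficients", call. = FALSE)
    }
  }
  structure(
    list(transform = transform, beta = fit$coefficients, residuals = res,
         smearing_model = smear, heteroscedastic = heteroscedastic,
         column_names = colnames(X)),
    class = "transform_ols_fit"
  )
}

#' Retransform linear-model predictions to the cost scale
#'
#' @param fit A [fit_transform_ols()] object.
#' @param X_new Design matrix for prediction.
#' @return Mean-cost predictions: `X b` (identity); `exp(X b) * s(X)` (log),
#'   with the fitted smearing factor `s(X)` clipped below at `1e-6`;
#'   `(X b)^2 + s(X)` (sqrt), with `s(X)` clipped below at 0. Clipping guards
#'   against the linear projection of a positive quantity going negative in
#'   the tails of the covariate space.
#' @export
retransform_predict <- function(fit, X_new) {
  stopifnot(inherits(fit, "transform_ols_fit"))
  X_new <- as.matrix(X_new)
  idx <- drop(X_new %*% fit$beta)
  if (fit$transform == "identity") return(idx)
  s <- drop(X_new %*% fit$smearing_model)
  if (any(!is.finite(s))) stop("non-finite smearing fitted values", call. = FALSE)
  if (fit$transform == "log") exp(idx) * pmax(s, 1e-6) else idx^2 + pmax(s, 0)
}
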