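# Quasi-Monte-Carlo experiment: a synthetic population is split once into
# an estimation half and a validation half; for each sample size Ns and
# replication r a with-replacement sample of size Ns is drawn from the
# estimation half, every requested model is fitted on it, and mean-cost
# forecasts are scored on the full validation half. Replications are only
# included in summaries when every requested model converged.

#' Configuration for a quasi-Monte-Carlo experiment
#'
#' @param population_size Number of records in the synthetic population
#'   (ignored when `population` is supplied to [run_experiment()]).
#' @param sample_sizes Estimation sample sizes `Ns`.
#' @param replications Replications per sample size.
#' @param models Subset of [cost_models()].
#' @param master_seed Master seed; every replication derives its own seed as
#'   a pure function of `(master_seed, Ns, r)`, so results do not depend on
#'   execution order.
#' @param dgp A [dgp_config()] for the population (default:
#'   [heavy_tail_dgp()]).
#' @param n_morbidity Morbidity markers in the generated design.
#' @param Q Interval count for the conditional density estimators.
#' @param deciles If `TRUE`, collect per-replication decile profiles.
#' @return Object of class `harness_config`.
#' @export
harness_config <- function(population_size = 200000L,
                           sample_sizes = c(1000L, 5000L),
                           replications = 20L,
                           models = c("OLS", "LOGOLSHET", "SQRTOLSHET",
                                      "GLMLOGP", "GLMLOGG", "GLMSQRTP",
                                      "GLMSQRTG", "LOGNORM"),
                           master_seed = 1L, dgp = NULL,
                           n_morbidity = 24L, Q = 15L, deciles = FALSE) {
  models <- match.arg(models, cost_models(), several.ok = TRUE)
  if (replications < 1L) stop("need at least one replication", call. = FALSE)
  if (max(sample_sizes) > population_size %/% 2) {
    stop("sample sizes must not exceed the estimation-set size", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         sample_sizes = as.integer(sample_sizes),
         replications = as.integer(replications), models = models,
         master_seed = as.integer(master_seed), dgp = dgp,
         n_morbidity = as.integer(n_morbidity), Q = as.integer(Q),
         deciles = isTRUE(deciles)),
    class = "harness_config"
  )
}

fit_one_model <- function(sample_data, model, Q) {
  out <- tryCatch(cost_reg(sample_data, model, Q = Q),
                  error = function(e) NULL)
  if (is.null(out) || !isTRUE(out$converged)) return(NULL)
  out
}

#' Run the quasi-Monte-Carlo experiment
#'
#' @param config A [harness_config()].
#' @param population Optional [cost_dataset()] to use as the population;
#'   when omitted one is generated from `config$dgp` (default heavy-tailed
#'   process) with `config$master_seed`.
#' @return Object of class `harness_result` with `records` (metric rows per
#'   model x Ns x replication, with ADMPE), `pearson` (in-sample test rows),
#'   `convergence` (flags per model x Ns x replication, with the joint
#'   `included` flag), optional `decile_profiles`, and the `config`.
#' @export
run_experiment <- function(config, population = NULL) {
  stopifnot(inherits(config, "harness_config"))
  if (is.null(population)) {
    spec <- covariate_spec(n = config$population_size,
                           n_morbidity = config$n_morbidity)
    X <- make_covariates(spec, seed = config$master_seed)
    dgp <- config$dgp %||% heavy_tail_dgp(seed = config$master_seed + 1L,
                                          n_morbidity = config$n_morbidity)
    population <- simulate_costs(X, dgp)
  }
  halves <- split_population(population, seed = config$master_seed + 2L)
  est <- halves$estimation
  val <- halves$validation
  n_est <- length(est$y)
  records <- list()
  pearson <- list()
  conv <- list()
  dec_prof <- list()
  for (ns in config$sample_sizes) {
    for (r in seq_len(config$replications)) {
      seed_r <- child_seed(config$master_seed, ns, r)
      set.seed(seed_r)
      rows <- sample.int(n_est, ns, replace = TRUE)
      samp <- cost_dataset(est$X[rows, , drop = FALSE], est$y[rows])
      fits <- lapply(config$models, fit_one_model, sample_data = samp,
                     Q = config$Q)
      names(fits) <- config$models
      ok <- !vapply(fits, is.null, logical(1))
      conv[[length(conv) + 1L]] <- data.frame(
        model = config$models, Ns = ns, replication = r, converged = ok,
        included = all(ok), stringsAsFactors = FALSE)
      for (m in config$models[ok]) {
        yhat_val <- predict(fits[[m]], val$X)
        records[[length(records) + 1L]] <-
          compute_metrics(val$y, yhat_val, model = m, Ns = ns, r = r)
        pt <- pearson_test(samp$y, predict(fits[[m]], samp$X))
        pearson[[length(pearson) + 1L]] <- data.frame(
          model = m, Ns = ns, replication = r, slope = pt$slope,
          p_value = pt$p_value, reject_5pct = pt$reject_5pct,
          applicable = pt$applicable, stringsAsFactors = FALSE)
        if (config$deciles) {
          dp <- decile_profile(val$y, yhat_val, model = m)
          dp$Ns <- ns; dp$replication <- r
          dec_prof[[length(dec_prof) + 1L]] <- dp
        }
      }
    }
  }
  records <- add_admpe(do.call(rbind, records))
  structure(
    list(records = records, pearson = do.call(rbind, pearson),
         convergence = do.call(rbind, conv),
         decile_profiles = if (config$deciles) do.call(rbind, dec_prof),
         config = config),
    class = "harness_result"
  )
}

#' Summarize a quasi-Monte-Carlo experiment
#'
#' Averages MPE / MAPE / RMSE / ADMPE per model and sample size over the
#' replications in which every requested model converged, reports Pearson
#' rejection percentages on the same replications, and flags the four best
#' models per metric (smallest |MPE|, MAPE, RMSE).
#'
#' @param results A [run_experiment()] result.
#' @return List of class `harness_summary` with `table` (per model x Ns),
#'   `pearson` (rejection percentages), `included` (replications kept per
#'   Ns out of the total).
#' @export
summarize_experiment <- function(results) {
  stopifnot(inherits(results, "harness_result"))
  cv <- results$convergence
  inc <- unique(cv[cv$included, c("Ns", "replication")])
  if (nrow(inc) == 0L) {
    stop("no replication had all requested models converge", call. = FALSE)
  }
  rec <- merge(results$records, inc, by = c("Ns", "replication"))
  # ADMPE is defined relative to the included replications
  rec$admpe <- NULL
  rec <- add_admpe(rec)
  agg <- stats::aggregate(rec[c("mpe", "mape", "rmse", "admpe")],
                          by = rec[c("model", "Ns")], FUN = mean)
  agg <- agg[order(agg$Ns, agg$model), ]
  rownames(agg) <- NULL
  for (met in c("mape", "rmse")) {
    agg[[paste0("best4_", met)]] <- stats::ave(
      agg[[met]], agg$Ns, FUN = function(v) rank(v, ties.method = "first") <= 4)
  }
  agg$best4_mpe <- stats::ave(
    abs(agg$mpe), agg$Ns, FUN = function(v) rank(v, ties.method = "first") <= 4)
  pe <- merge(results$pearson, inc, by = c("Ns", "replication"))
  pe_agg <- stats::aggregate(
    list(reject_pct = pe$reject_5pct),
    by = pe[c("model", "Ns")],
    FUN = function(v) 100 * mean(v, na.rm = TRUE))
  included <- stats::aggregate(
    list(included = inc$replication),
    by = inc["Ns"], FUN = length)
  included$total <- results$config$replications
  structure(list(table = agg, pearson = pe_agg, included = included),
            class = "harness_summary")
}

#' @export
print.harness_summary <- function(x, digits = 2, ...) {
  cat("Quasi-Monte-Carlo summary (averages over included replications)\n")
  print(format(x$table, digits = digits), ...)
  cat("\nPearson test rejection rates (%):\n")
  print(format(x$pearson, digits = digits), ...)
  cat("\nIncluded replications:\n")
  print(x$included, ...)
  invisible(x)
}

#' Response surfaces for every model and metric in a result
#'
#' @param results A [run_experiment()] result covering at least two sample
#'   sizes.
#' @param metrics Metrics to fit surfaces for.
#' @return Data frame with one row per model x metric: `alpha`,
#'   `beta_inv_n`, `alpha_p_value`, `log_scale`.
#' @export
experiment_surfaces <- function(results,
                                metrics = c("mpe", "mape", "rmse", "admpe")) {
  stopifnot(inherits(results, "harness_result"))
  cv <- results$convergence
  inc <- unique(cv[cv$included, c("Ns", "replication")])
  rec <- merge(results$records, inc, by = c("Ns", "replication"))
  rec$admpe <- NULL
  rec <- add_admpe(rec)
  rows <- list()
  for (m in unique(rec$model)) {
    for (met in metrics) {
      rs <- tryCatch(fit_response_surface(rec, m, met),
                     error = function(e) NULL)
      if (is.null(rs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, metric = met, alpha = rs$alpha,
        beta_inv_n = rs$beta_inv_n, alpha_se = rs$alpha_se,
        alpha_p_value = rs$alpha_p_value, log_scale = rs$log_scale,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write experiment outputs as CSV
#'
#' @param results A [run_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_csv <- function(results, dir) {
  stopifnot(inherits(results, "harness_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(results$records, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(results$pearson, file.path(dir, "pearson.csv"),
                   row.names = FALSE)
  utils::write.csv(results$convergence, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  if (!is.null(results$decile_profiles)) {
    utils::write.csv(results$decile_profiles,
                     file.path(dir, "decile_profiles.csv"), row.names = FALSE)
  }
  invisible(dir)
}
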