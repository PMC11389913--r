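# Forecast evaluation: MSE on the mmol/L scale, a naive persistence
# reference, the six-model x three-horizon comparison protocol, and a
# normal Q-Q diagnostic of forecast residuals.

#' Paired forecasts and actuals at one horizon
#'
#' @param horizon_min Prediction horizon PH in minutes.
#' @param predictions Predicted glucose `yhat(t | t - PH)` in mmol/L.
#' @param actuals Measured glucose `y(t)` in mmol/L.
#' @param target_times Instants `t` of the targets.
#' @return A `forecast_result` list.
#' @export
forecast_result <- function(horizon_min, predictions, actuals, target_times) {
  n <- length(predictions)
  if (n < 1 || length(actuals) != n || length(target_times) != n) {
    stop_cgm("predictions, actuals and target_times must share length >= 1",
             class = "cgm_parameter_error")
  }
  structure(list(horizon_min = horizon_min, predictions = as.numeric(predictions),
                 actuals = as.numeric(actuals), target_times = target_times),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> PH=%d min, N=%d, MSE=%.4f (mmol/L)^2\n",
              x$horizon_min, length(x$predictions), mse(x)))
  invisible(x)
}

#' Mean squared forecast error
#'
#' `MSE = (1/N) * sum((yhat(t | t - PH) - y(t))^2)`, reported in (mmol/L)^2.
#'
#' @param result A [forecast_result()].
#' @return Nonnegative scalar; 0 iff predictions equal actuals.
#' @export
mse <- function(result) {
  stopifnot(inherits(result, "forecast_result"))
  if (length(result$predictions) < 1) stop_cgm("empty forecast result", class = "cgm_parameter_error")
  mean((result$predictions - result$actuals)^2)
}

#' Persistence (last-value) baseline forecast
#'
#' The naive reference that repeats the last observed value of each input
#' window; any trained model must beat it to have demonstrated skill.
#'
#' @param windows Unscaled `supervised_windows`.
#' @return A [forecast_result()].
#' @export
persistence_forecast <- function(windows) {
  stopifnot(inherits(windows, "supervised_windows"))
  if (windows$scaled) stop_cgm("persistence_forecast expects unscaled windows",
                               class = "cgm_contract_error")
  L <- windows$spec$lookback_steps
  forecast_result(
    horizon_min = windows$spec$horizon_steps * windows$spec$interval_min,
    predictions = windows$inputs[, L],
    actuals = windows$targets,
    target_times = windows$target_times
  )
}

#' Normal Q-Q diagnostic of forecast residuals
#'
#' Residuals `e = yhat - y` are standardized and their order statistics are
#' paired with standard normal quantiles at the Hazen probability points
#' `(i - 0.5) / N`. The correlation `r` of the pairs is a scalar normality
#' index (close to 1 when residuals are Gaussian).
#'
#' @param result A [forecast_result()] with at least 3 pairs.
#' @return A `qq_report` with `theoretical_quantiles`, `sample_quantiles`,
#'   `r` and `n`.
#' @export
qq_normality <- function(result) {
  stopifnot(inherits(result, "forecast_result"))
  e <- result$predictions - result$actuals
  n <- length(e)
  if (n < 3) stop_cgm("need at least 3 residuals for a Q-Q report", class = "cgm_insufficient_data")
  s <- stats::sd(e)
  if (!is.finite(s) || s == 0) {
    stop_cgm("residuals have zero variance; Q-Q plot undefined", class = "cgm_degenerate_input")
  }
  z <- sort((e - mean(e)) / s)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  structure(list(theoretical_quantiles = theo, sample_quantiles = z,
                 r = stats::cor(theo, z), n = n),
            class = "qq_report")
}

#' @export
print.qq_report <- function(x, ...) {
  cat(sprintf("<qq_report> n=%d, r=%.4f\n", x$n, x$r))
  invisible(x)
}

#' Cohort-level supervised windows with a per-patient chronological split
#'
#' Regularizes each patient's trace, builds windows per segment, splits each
#' patient chronologically, then pools the training (and test) windows
#' across patients — the dataset protocol used by [evaluate_horizons()].
#'
#' @param cohort List of [glucose_series()].
#' @param spec A [window_spec()].
#' @param train_frac Chronological train fraction per patient.
#' @param interval_min,max_gap_min Passed to [regularize()].
#' @return `list(train, test)` of pooled `supervised_windows`.
#' @export
cohort_split_windows <- function(cohort, spec, train_frac = 0.8,
                                 interval_min = spec$interval_min,
                                 max_gap_min = 15) {
  trains <- list(); tests <- list()
  for (s in cohort) {
    segs <- regularize(s, interval_min = interval_min, max_gap_min = max_gap_min)
    w <- tryCatch(make_windows(segs, spec), cgm_empty_dataset = function(e) NULL)
    if (is.null(w)) next
    sp <- tryCatch(chronological_split(w, train_frac), cgm_parameter_error = function(e) NULL)
    if (is.null(sp)) next
    trains[[length(trains) + 1L]] <- sp$train
    tests[[length(tests) + 1L]] <- sp$test
  }
  if (length(trains) == 0) stop_cgm("no patient yielded a train/test split", class = "cgm_empty_dataset")
  list(train = windows_rbind(trains), test = windows_rbind(tests))
}

#' Compare model kinds across prediction horizons
#'
#' The full comparison protocol: for every (kind, horizon) cell, build
#' windows at `H = horizon / interval`, split chronologically per patient,
#' standardize with a train-fit scaler, train the model, forecast the test
#' split and compute MSE in (mmol/L)^2. A cell whose training fails is
#' recorded as `NA` and flagged; the run continues.
#'
#' @param cohort List of [glucose_series()].
#' @param kinds Character vector of model kinds (see [build_model()]).
#' @param horizons_min Horizons in minutes, each divisible by the sampling
#'   interval.
#' @param lookback Input window length L in samples.
#' @param model_cfg A [hybrid_config()] (its `lookback` is overridden).
#' @param train_cfg A [train_config()].
#' @param train_frac Chronological train fraction per patient.
#' @param seed Master seed; per-cell model/training seeds are derived.
#' @param interval_min Sampling grid in minutes.
#' @param max_test_windows Optional deterministic cap on test windows per
#'   cell (even thinning), for desk-scale runs.
#' @return A `comparison_table`: data.frame with rows = kinds, columns =
#'   horizons, cells = test MSE; attributes `metadata` (seed, digest,
#'   per-cell seeds) and `failed` (logical matrix), plus per-cell forecasts
#'   in attribute `forecasts` (named `kind_horizon`).
#' @export
evaluate_horizons <- function(cohort, kinds = MODEL_KINDS,
                              horizons_min = c(15, 30, 45), lookback = 12L,
                              model_cfg = hybrid_config(), train_cfg = train_config(),
                              train_frac = 0.8, seed = 1L, interval_min = 5L,
                              max_test_windows = Inf) {
  stopifnot(all(kinds %in% MODEL_KINDS))
  if (any(horizons_min %% interval_min != 0)) {
    stop_cgm("every horizon must be divisible by interval_min = %d", interval_min,
             class = "cgm_parameter_error")
  }
  model_cfg$lookback <- as.integer(lookback)
  tab <- matrix(NA_real_, length(kinds), length(horizons_min),
                dimnames = list(kinds, paste0(horizons_min, "min")))
  failed <- matrix(FALSE, length(kinds), length(horizons_min),
                   dimnames = dimnames(tab))
  forecasts <- list()
  cell_seeds <- tab
  for (j in seq_along(horizons_min)) {
    H <- horizons_min[j] %/% interval_min
    spec <- window_spec(lookback, H, interval_min)
    sp <- cohort_split_windows(cohort, spec, train_frac, interval_min)
    scaler <- fit_scaler(sp$train)
    tr_s <- apply_scaler(sp$train, scaler)
    te <- thin_windows(sp$test, max_test_windows)
    te_s <- apply_scaler(te, scaler)
    for (i in seq_along(kinds)) {
      cell_seed <- derive_seed(seed, i * 100L + j)
      cell_seeds[i, j] <- cell_seed
      res <- tryCatch({
        cfg_t <- train_cfg
        cfg_t$seed <- cell_seed
        m <- build_model(kinds[i], model_cfg, seed = cell_seed)
        tr <- train(m, tr_s, cfg_t)
        predict(tr$model, te_s, scaler)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed[i, j] <- TRUE
        warning(sprintf("cell %s @ %dmin failed: %s", kinds[i], horizons_min[j],
                        conditionMessage(res)))
      } else {
        tab[i, j] <- mse(res)
        forecasts[[paste0(kinds[i], "_", horizons_min[j])]] <- res
      }
    }
  }
  out <- as.data.frame(tab)
  attr(out, "metadata") <- list(
    seed = seed, kinds = kinds, horizons_min = horizons_min,
    lookback = lookback, cell_seeds = cell_seeds,
    n_patients = length(cohort),
    digest = config_digest(list(kinds = kinds, horizons = horizons_min,
                                lookback = lookback, seed = seed,
                                model_cfg = unclass(model_cfg),
                                train_cfg = unclass(train_cfg)))
  )
  attr(out, "failed") <- failed
  attr(out, "forecasts") <- forecasts
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write / read a comparison table as CSV
#'
#' The CSV round-trips the numeric grid (`model` column + one column per
#' horizon); metadata is written alongside as JSON if `json_path` is given.
#'
#' @param tab A `comparison_table`.
#' @param path CSV output path.
#' @param json_path Optional JSON path for grid + metadata.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(tab, path, json_path = NULL) {
  stopifnot(inherits(tab, "comparison_table"))
  df <- data.frame(model = rownames(tab), tab, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(json_path)) {
    md <- attr(tab, "metadata")
    md$cell_seeds <- NULL
    jsonlite::write_json(list(grid = df, metadata = md), json_path,
                         auto_unbox = TRUE, digits = 10)
  }
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rn <- df$model
  df$model <- NULL
  rownames(df) <- rn
  class(df) <- c("comparison_table", "data.frame")
  df
}
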