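# Supervised dataset construction: sliding windows over regular segments,
# leak-free chronological splits and reversible standardization. Window
# inputs are L consecutive samples; the target is the sample H steps after
# the window's last element (direct multi-horizon forecasting, one model per
# horizon: 15/30/45 min = H in {3, 6, 9} at 5-minute sampling).

#' Window specification
#'
#' @param lookback_steps History length L in samples (default 12 = 60 min at
#'   5-minute sampling).
#' @param horizon_steps Forecast lead H in samples.
#' @param interval_min Sampling interval of the underlying grid in minutes.
#' @return A `window_spec` list.
#' @export
window_spec <- function(lookback_steps = 12L, horizon_steps = 3L, interval_min = 5L) {
  if (!is_count(lookback_steps) || !is_count(horizon_steps) || !is_count(interval_min)) {
    stop_cgm("lookback_steps, horizon_steps and interval_min must be positive integers",
             class = "cgm_parameter_error")
  }
  structure(list(lookback_steps = as.integer(lookback_steps),
                 horizon_steps = as.integer(horizon_steps),
                 interval_min = as.integer(interval_min)),
            class = "window_spec")
}

new_supervised_windows <- function(inputs, targets, target_times, spec, scaled,
                                   scaler = NULL) {
  structure(list(inputs = inputs, targets = targets, target_times = target_times,
                 spec = spec, scaled = scaled, scaler = scaler),
            class = "supervised_windows")
}

#' Build supervised windows from regular segments
#'
#' Windows never span segment boundaries, so every input precedes its target
#' on the same uninterrupted grid: window i covers steps `[i, i+L)` of a
#' segment and its target is step `i + L + H - 1` (0-based), giving
#' `n - L - H + 1` windows per segment of length n.
#'
#' @param segments A list of [glucose_series()] on the `spec$interval_min`
#'   grid (see [regularize()]), or a single series.
#' @param spec A [window_spec()].
#' @return A `supervised_windows` object with fields `inputs`
#'   (n_windows x L matrix), `targets`, `target_times`, `spec`, `scaled`.
#' @export
make_windows <- function(segments, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  if (inherits(segments, "glucose_series")) segments <- list(segments)
  L <- spec$lookback_steps; H <- spec$horizon_steps
  ins <- list(); tgt <- list(); tt <- list()
  for (seg in segments) {
    stopifnot(inherits(seg, "glucose_series"))
    n <- length(seg$glucose)
    nw <- n - L - H + 1L
    if (nw < 1) next
    idx <- outer(seq_len(nw) - 1L, seq_len(L), `+`)
    ins[[length(ins) + 1L]] <- matrix(seg$glucose[idx], nrow = nw, ncol = L)
    tgt[[length(tgt) + 1L]] <- seg$glucose[(L + H):(L + H + nw - 1L)]
    tt[[length(tt) + 1L]] <- seg$timestamps[(L + H):(L + H + nw - 1L)]
  }
  if (length(ins) == 0) {
    stop_cgm("all segments shorter than lookback + horizon (%d)", L + H,
             class = "cgm_empty_dataset")
  }
  new_supervised_windows(
    inputs = do.call(rbind, ins),
    targets = unlist(tgt, use.names = FALSE),
    target_times = do.call(c, tt),
    spec = spec, scaled = FALSE
  )
}

#' @export
print.supervised_windows <- function(x, ...) {
  cat(sprintf("<supervised_windows> %d windows, L=%d, H=%d (%d min ahead)%s\n",
              nrow(x$inputs), x$spec$lookback_steps, x$spec$horizon_steps,
              x$spec$horizon_steps * x$spec$interval_min,
              if (x$scaled) " [scaled]" else ""))
  invisible(x)
}

windows_subset <- function(w, idx) {
  new_supervised_windows(w$inputs[idx, , drop = FALSE], w$targets[idx],
                         w$target_times[idx], w$spec, w$scaled, w$scaler)
}

windows_rbind <- function(ws) {
  ws <- ws[!vapply(ws, is.null, logical(1))]
  stopifnot(length(ws) >= 1)
  new_supervised_windows(
    do.call(rbind, lapply(ws, `[[`, "inputs")),
    unlist(lapply(ws, `[[`, "targets"), use.names = FALSE),
    do.call(c, lapply(ws, `[[`, "target_times")),
    ws[[1]]$spec, ws[[1]]$scaled, ws[[1]]$scaler
  )
}

#' Chronological train/test split
#'
#' Orders windows by target time and assigns the first
#' `floor(train_frac * n)` to the training side, so every training target
#' precedes every test target (no temporal leakage).
#'
#' @param w A `supervised_windows` object.
#' @param train_frac Fraction in (0, 1) assigned to training.
#' @return A list with elements `train` and `test`.
#' @export
chronological_split <- function(w, train_frac = 0.8) {
  stopifnot(inherits(w, "supervised_windows"))
  n <- nrow(w$inputs)
  if (n < 2) stop_cgm("need at least 2 windows to split", class = "cgm_parameter_error")
  if (train_frac <= 0 || train_frac >= 1) {
    stop_cgm("train_frac must be in (0, 1)", class = "cgm_parameter_error")
  }
  ord <- order(w$target_times)
  n_train <- floor(train_frac * n)
  if (n_train < 1 || n_train >= n) {
    stop_cgm("split would leave an empty side (n=%d, train_frac=%g)", n, train_frac,
             class = "cgm_parameter_error")
  }
  list(train = windows_subset(w, ord[seq_len(n_train)]),
       test = windows_subset(w, ord[(n_train + 1):n]))
}

#' Fit a standardizing scaler on training windows
#'
#' Mean and SD are pooled over every entry of the training input matrix
#' (training data only, so no information from the test period leaks into
#' the transform).
#'
#' @param train A `supervised_windows` object (unscaled).
#' @return A `cgm_scaler` with fields `mean` and `sd` (mmol/L).
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "supervised_windows"))
  if (train$scaled) stop_cgm("scaler must be fit on unscaled windows", class = "cgm_contract_error")
  m <- mean(train$inputs)
  s <- stats::sd(as.vector(train$inputs))
  if (!is.finite(s) || s <= 0) {
    stop_cgm("training inputs are constant; cannot standardize", class = "cgm_constant_data")
  }
  structure(list(mean = m, sd = s), class = "cgm_scaler")
}

#' Apply a scaler to windows
#'
#' Standardizes both inputs and targets: `(x - mean) / sd`.
#'
#' @param w A `supervised_windows` object (unscaled).
#' @param scaler A `cgm_scaler` from [fit_scaler()].
#' @return Scaled `supervised_windows` (flag `scaled = TRUE`).
#' @export
apply_scaler <- function(w, scaler) {
  stopifnot(inherits(w, "supervised_windows"), inherits(scaler, "cgm_scaler"))
  if (w$scaled) stop_cgm("windows already scaled", class = "cgm_contract_error")
  new_supervised_windows((w$inputs - scaler$mean) / scaler$sd,
                         (w$targets - scaler$mean) / scaler$sd,
                         w$target_times, w$spec, scaled = TRUE, scaler = scaler)
}

#' Invert a scaler
#'
#' Maps scaled values back to mmol/L: `x * sd + mean`. Forecast errors are
#' always reported on this original scale.
#'
#' @param values Numeric vector/matrix in scaled units.
#' @param scaler A `cgm_scaler`.
#' @return Values in mmol/L.
#' @export
invert_scaler <- function(values, scaler) {
  stopifnot(inherits(scaler, "cgm_scaler"))
  values * scaler$sd + scaler$mean
}
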