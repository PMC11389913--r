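# CGM trace I/O: a documented CSV dialect, gap-aware regularization and
# descriptive statistics. A trace is one patient's timestamped glucose series
# in mmol/L; sensor-calibration blood-glucose entries are sparse and optional.

#' Construct a glucose series
#'
#' The universal I/O currency of the package: one patient's timestamped CGM
#' trace. Timestamps must be strictly increasing (UTC, second resolution),
#' glucose values finite and positive, all in mmol/L.
#'
#' @param patient_id Opaque patient identifier (single string).
#' @param timestamps `POSIXct` vector (coerced to UTC), strictly increasing.
#' @param glucose Numeric vector of sensor glucose in mmol/L.
#' @param calibration_bg Optional numeric vector of capillary calibration
#'   blood glucose in mmol/L, `NA` where absent (the common case).
#' @return An object of class `glucose_series`.
#' @export
glucose_series <- function(patient_id, timestamps, glucose, calibration_bg = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1 || is.na(patient_id)) {
    stop_cgm("patient_id must be a single string", class = "cgm_parameter_error")
  }
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  n <- length(timestamps)
  if (n < 1) stop_cgm("a glucose series needs at least one sample", class = "cgm_empty_input")
  if (length(glucose) != n) {
    stop_cgm("glucose length (%d) != timestamps length (%d)", length(glucose), n,
             class = "cgm_parameter_error")
  }
  if (is.null(calibration_bg)) calibration_bg <- rep(NA_real_, n)
  if (length(calibration_bg) != n) {
    stop_cgm("calibration_bg length (%d) != timestamps length (%d)",
             length(calibration_bg), n, class = "cgm_parameter_error")
  }
  if (anyNA(timestamps)) stop_cgm("timestamps contain NA", class = "cgm_format_error")
  d <- diff(as.numeric(timestamps))
  if (any(d == 0)) {
    dup <- timestamps[which(d == 0)[1] + 1]
    stop_cgm("duplicated timestamp: %s", format_utc(dup), class = "cgm_duplicate_timestamp")
  }
  if (any(d < 0)) stop_cgm("timestamps must be strictly increasing", class = "cgm_format_error")
  glucose <- as.numeric(glucose)
  if (!all(is.finite(glucose)) || any(glucose <= 0)) {
    stop_cgm("glucose values must be finite and > 0 mmol/L", class = "cgm_format_error")
  }
  structure(
    list(patient_id = patient_id, timestamps = timestamps,
         glucose = glucose, calibration_bg = as.numeric(calibration_bg)),
    class = "glucose_series"
  )
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> patient %s: %d samples, %s .. %s\n",
              x$patient_id, length(x$glucose),
              format_utc(x$timestamps[1]), format_utc(x$timestamps[length(x$timestamps)])))
  cat(sprintf("  glucose %.2f-%.2f mmol/L, %d calibration entries\n",
              min(x$glucose), max(x$glucose), sum(!is.na(x$calibration_bg))))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$glucose)

#' CSV dialect for CGM traces
#'
#' The canonical dialect is comma-separated with header
#' `patient_id,timestamp,glucose_mmol_l,calibration_bg_mmol_l` and ISO-8601
#' UTC timestamps. Device exports with other column names are handled by
#' remapping; `units = "mg_dl"` converts glucose columns by /18.016 at ingest.
#'
#' @param patient_col,time_col,glucose_col,calibration_col Column names.
#' @param units `"mmol_l"` (default) or `"mg_dl"`.
#' @param sep Field separator.
#' @return A `cgm_dialect` list.
#' @export
cgm_dialect <- function(patient_col = "patient_id", time_col = "timestamp",
                        glucose_col = "glucose_mmol_l",
                        calibration_col = "calibration_bg_mmol_l",
                        units = c("mmol_l", "mg_dl"), sep = ",") {
  units <- match.arg(units)
  structure(list(patient_col = patient_col, time_col = time_col,
                 glucose_col = glucose_col, calibration_col = calibration_col,
                 units = units, sep = sep),
            class = "cgm_dialect")
}

parse_utc <- function(x) {
  x <- sub("Z$", "", trimws(x))
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

#' Read a CGM trace from CSV
#'
#' Rows whose glucose cell is non-numeric, non-finite or not positive are
#' dropped with a warning stating the count; an unparseable timestamp or a
#' duplicated instant is an error. The result is sorted by time.
#'
#' @param path Path to an existing CSV file with a header row.
#' @param dialect A [cgm_dialect()].
#' @return A [glucose_series()].
#' @export
read_cgm_csv <- function(path, dialect = cgm_dialect()) {
  if (!file.exists(path)) stop_cgm("file not found: %s", path, class = "cgm_io_error")
  df <- utils::read.csv(path, sep = dialect$sep, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  for (col in c(dialect$time_col, dialect$glucose_col)) {
    if (!col %in% names(df)) {
      stop_cgm("required column '%s' missing from %s", col, path, class = "cgm_format_error")
    }
  }
  pid <- if (dialect$patient_col %in% names(df)) unique(df[[dialect$patient_col]]) else "unknown"
  if (length(pid) > 1) {
    stop_cgm("file contains %d patient ids; one series per file", length(pid),
             class = "cgm_format_error")
  }
  ts <- parse_utc(df[[dialect$time_col]])
  if (anyNA(ts)) {
    stop_cgm("unparseable timestamp at row %d", which(is.na(ts))[1], class = "cgm_format_error")
  }
  glu <- suppressWarnings(as.numeric(df[[dialect$glucose_col]]))
  cal <- if (dialect$calibration_col %in% names(df)) {
    suppressWarnings(as.numeric(df[[dialect$calibration_col]]))
  } else {
    rep(NA_real_, nrow(df))
  }
  if (dialect$units == "mg_dl") {
    glu <- glu / 18.016
    cal <- cal / 18.016
  }
  keep <- is.finite(glu) & glu > 0
  n_bad <- sum(!keep)
  if (n_bad > 0) {
    warning(sprintf("read_cgm_csv: dropped %d row(s) with invalid glucose in %s", n_bad, path))
  }
  if (!any(keep)) stop_cgm("no valid glucose rows in %s", path, class = "cgm_empty_input")
  ord <- order(ts[keep])
  glucose_series(patient_id = as.character(pid),
                 timestamps = ts[keep][ord],
                 glucose = glu[keep][ord],
                 calibration_bg = cal[keep][ord])
}

#' Write a CGM trace to CSV
#'
#' Uses the canonical dialect header; glucose is written with 4 decimal
#' places and timestamps as ISO-8601 UTC, so a read/write round-trip is
#' lossless at that declared precision.
#'
#' @param series A [glucose_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  if (length(series$glucose) == 0) stop_cgm("refusing to write an empty series", class = "cgm_empty_input")
  df <- data.frame(
    patient_id = series$patient_id,
    timestamp = format_utc(series$timestamps),
    glucose_mmol_l = sprintf("%.4f", series$glucose),
    calibration_bg_mmol_l = ifelse(is.na(series$calibration_bg), "",
                                   sprintf("%.4f", series$calibration_bg)),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_cgm("cannot write to %s", path, class = "cgm_io_error")
  invisible(path)
}

#' Regularize a CGM trace onto a fixed sampling grid
#'
#' CGM sensors nominally report every 5 minutes but transmission loss leaves
#' gaps. Gaps no longer than `max_gap_min` are bridged by linear
#' interpolation; longer gaps split the trace into separate segments (the
#' 15-minute default mirrors the sensor-to-capillary trust horizon).
#' Calibration entries are carried to the nearest grid instant.
#'
#' @param series A [glucose_series()].
#' @param interval_min Grid spacing in minutes (default 5).
#' @param max_gap_min Longest gap, in minutes, bridged by interpolation.
#' @return A list of `glucose_series` segments, each on an exact
#'   `interval_min` grid and at least 2 samples long.
#' @export
regularize <- function(series, interval_min = 5, max_gap_min = 15) {
  stopifnot(inherits(series, "glucose_series"))
  if (!is.numeric(interval_min) || length(interval_min) != 1 || interval_min <= 0) {
    stop_cgm("interval_min must be a positive number", class = "cgm_parameter_error")
  }
  rel <- as.numeric(difftime(series$timestamps, series$timestamps[1], units = "mins"))
  n <- length(rel)
  breaks <- which(diff(rel) > max_gap_min + 1e-9)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- list()
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    span <- rel[b] - rel[a]
    n_grid <- floor(span / interval_min + 1e-9) + 1
    if (n_grid < 2) next
    grid <- rel[a] + (seq_len(n_grid) - 1) * interval_min
    vals <- if (b - a >= 1) {
      stats::approx(rel[a:b], series$glucose[a:b], xout = grid)$y
    } else {
      series$glucose[a]
    }
    cal <- rep(NA_real_, n_grid)
    has_cal <- which(!is.na(series$calibration_bg[a:b])) + a - 1L
    for (i in has_cal) {
      j <- which.min(abs(grid - rel[i]))
      if (abs(grid[j] - rel[i]) <= interval_min / 2 && is.na(cal[j])) {
        cal[j] <- series$calibration_bg[i]
      }
    }
    out[[length(out) + 1L]] <- glucose_series(
      patient_id = series$patient_id,
      timestamps = series$timestamps[1] + grid * 60,
      glucose = vals,
      calibration_bg = cal
    )
  }
  if (length(out) == 0) {
    stop_cgm("regularize produced no segment of length >= 2", class = "cgm_empty_input")
  }
  out
}

#' Descriptive statistics of a glucose series
#'
#' Exact sample statistics of the glucose column; `sd` uses the sample
#' (n-1) convention.
#'
#' @param series A [glucose_series()].
#' @return A `series_summary` list with fields `n`, `mean`, `sd`, `min`,
#'   `max` (mmol/L) and `n_calibration`.
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  g <- series$glucose
  if (length(g) < 2) {
    stop_cgm("need at least 2 samples for a sample standard deviation",
             class = "cgm_insufficient_data")
  }
  structure(
    list(n = length(g), mean = mean(g), sd = stats::sd(g),
         min = min(g), max = max(g),
         n_calibration = sum(!is.na(series$calibration_bg))),
    class = "series_summary"
  )
}

#' Pooled descriptive statistics of a cohort
#'
#' Pools the glucose columns of all series and computes the same statistics
#' as [summarize_series()] on the pooled vector.
#'
#' @param cohort A list of [glucose_series()].
#' @return A `series_summary`.
#' @export
pooled_summary <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) >= 1)
  g <- unlist(lapply(cohort, function(s) s$glucose), use.names = FALSE)
  cal <- unlist(lapply(cohort, function(s) s$calibration_bg), use.names = FALSE)
  if (length(g) < 2) stop_cgm("need at least 2 pooled samples", class = "cgm_insufficient_data")
  structure(
    list(n = length(g), mean = mean(g), sd = stats::sd(g),
         min = min(g), max = max(g), n_calibration = sum(!is.na(cal))),
    class = "series_summary"
  )
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("n=%d  mean=%.2f  sd=%.2f  min=%.2f  max=%.2f mmol/L  (%d calibration)\n",
              x$n, x$mean, x$sd, x$min, x$max, x$n_calibration))
  invisible(x)
}

#' Serialize a summary to JSON
#' @param x A `series_summary`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
summary_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "series_summary"))
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = 10)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
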