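test_that("glucose_series enforces its invariants", {
  expect_s3_class(make_series(c(5, 6, 7)), "glucose_series")
  # duplicate timestamp error names the offending instant
  ts <- t0_utc + c(0, 300, 300, 600)
  err <- expect_error(glucose_series("P01", ts, c(5, 6, 7, 8)),
                      class = "cgm_duplicate_timestamp")
  expect_match(conditionMessage(err), "2022-03-01T00:05:00Z", fixed = TRUE)
  expect_error(glucose_series("P01", t0_utc + c(600, 300, 0), c(5, 6, 7)), class = "cgm_format_error")
  expect_error(glucose_series("P01", ts[1:2], c(5, -1)), class = "cgm_format_error")
  expect_error(glucose_series("P01", ts[1:2], c(5, NA)), class = "cgm_format_error")
  expect_error(glucose_series("P01", ts[1:2], 5), class = "cgm_parameter_error")
})

test_that("read_cgm_csv parses the canonical dialect and drops bad glucose rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,timestamp,glucose_mmol_l,calibration_bg_mmol_l",
    "P07,2022-03-01T00:00:00Z,8.3200,",
    "P07,2022-03-01T00:05:00Z,9.1000,8.9000",
    "P07,2022-03-01T00:10:00Z,7.5000,"
  ), path)
  s <- read_cgm_csv(path)
  expect_identical(s$patient_id, "P07")
  expect_identical(s$glucose, c(8.32, 9.1, 7.5))
  expect_identical(s$calibration_bg, c(NA, 8.9, NA))
  expect_identical(as.numeric(diff(s$timestamps), units = "mins"), c(5, 5))

  # one non-numeric glucose cell among 10 rows -> 9 rows kept, warning logged
  rows <- sprintf("P07,2022-03-01T%02d:%02d:00Z,%.4f,", (0:9) %/% 12, ((0:9) %% 12) * 5,
                  seq(5, 9.5, by = 0.5))
  rows[4] <- sub("[0-9.]+,$", "sensor_error,", rows[4])
  writeLines(c("patient_id,timestamp,glucose_mmol_l,calibration_bg_mmol_l", rows), path)
  expect_warning(s9 <- read_cgm_csv(path), "dropped 1 row")
  expect_identical(length(s9), 9L)

  writeLines(c("patient_id,timestamp", "P07,2022-03-01T00:00:00Z"), path)
  expect_error(read_cgm_csv(path), class = "cgm_format_error")
  writeLines(c("patient_id,timestamp,glucose_mmol_l,calibration_bg_mmol_l",
               "P07,2022-03-01T00:00:00Z,not_a_number,"), path)
  expect_warning(expect_error(read_cgm_csv(path), class = "cgm_empty_input"))
})

test_that("mg/dL ingest converts to mmol/L", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,glucose_mg_dl,calibration",
               "P01,2022-03-01T00:00:00Z,180.16,",
               "P01,2022-03-01T00:05:00Z,90.08,"), path)
  s <- read_cgm_csv(path, cgm_dialect(glucose_col = "glucose_mg_dl",
                                      calibration_col = "calibration",
                                      units = "mg_dl"))
  expect_equal(s$glucose, c(10, 5), tolerance = 1e-12)
})

test_that("write/read round-trip is lossless at 4-decimal precision", {
  prof <- patient_profile(seed = 3)
  s <- simulate_patient(prof, days = 2, patient_id = "P03")
  expect_identical(length(s), 576L)
  s$glucose <- round(s$glucose, 4) # declared precision of the dialect
  s$calibration_bg[c(10, 400)] <- c(7.25, 9.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cgm_csv(s, path)
  s2 <- read_cgm_csv(path)
  expect_identical(s2$glucose, s$glucose)
  expect_identical(s2$calibration_bg, s$calibration_bg)
  expect_equal(as.numeric(s2$timestamps), as.numeric(s$timestamps))
  # calibration column present with blanks for missing entries
  lines <- readLines(path)
  expect_match(lines[1], "calibration_bg_mmol_l")
  expect_match(lines[2], ",$")
})

test_that("regularize interpolates short gaps and splits long ones", {
  # one missing 5-min slot: midpoint filled by linear interpolation
  g <- c(5, 6, 8, 9)
  s <- glucose_series("P01", t0_utc + c(0, 5, 15, 20) * 60, g)
  segs <- regularize(s)
  expect_length(segs, 1)
  expect_identical(segs[[1]]$glucose, c(5, 6, 7, 8, 9))

  # 20-min gap with max_gap 15 -> 2 segments, lengths sum to original count
  s2 <- glucose_series("P01", t0_utc + c(0, 5, 10, 30, 35, 40) * 60, 1:6 + 0)
  segs2 <- regularize(s2)
  expect_length(segs2, 2)
  expect_identical(sum(vapply(segs2, length, integer(1))), length(s2))
  expect_identical(segs2[[1]]$glucose, c(1, 2, 3))
  expect_identical(segs2[[2]]$glucose, c(4, 5, 6))

  # already-regular series comes back unchanged as one segment
  s3 <- make_series(c(5, 5.5, 6, 6.5))
  segs3 <- regularize(s3)
  expect_length(segs3, 1)
  expect_identical(segs3[[1]]$glucose, s3$glucose)
  expect_equal(as.numeric(segs3[[1]]$timestamps), as.numeric(s3$timestamps))

  expect_error(regularize(s3, interval_min = 0), class = "cgm_parameter_error")
})

test_that("regularize output is on-grid and never drops interior points", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    keep <- sort(sample(n, max(4, round(n * 0.8))))
    vals <- 6 + cumsum(rnorm(n, 0, 0.2))
    s <- glucose_series("P01", t0_utc + (keep - 1) * 300, vals[keep])
    segs <- regularize(s, 5, 15)
    t0 <- s$timestamps[1]
    for (seg in segs) {
      rel <- as.numeric(difftime(seg$timestamps, t0, units = "mins"))
      expect_true(all(abs(rel %% 5) < 1e-9))
    }
    expect_gte(sum(vapply(segs, length, integer(1))), length(s))
  }
})

test_that("summaries are exact sample statistics", {
  expect_equal(unclass(summarize_series(make_series(c(2, 4, 6))))[1:5],
               list(n = 3L, mean = 4, sd = 2, min = 2, max = 6))
  expect_identical(summarize_series(make_series(c(5, 5, 5)))$sd, 0)
  expect_error(summarize_series(make_series(5)), class = "cgm_insufficient_data")

  # agrees with an independent streaming-moments oracle
  set.seed(7)
  for (rep in 1:100) {
    x <- runif(sample(2:50, 1), 3, 15)
    sm <- summarize_series(make_series(x))
    or <- welford(x)
    expect_equal(sm$mean, or$mean, tolerance = 1e-9)
    expect_equal(sm$sd, or$sd, tolerance = 1e-9)
  }
})

test_that("pooled_summary pools glucose and counts calibration entries", {
  cal <- rep(NA_real_, 4); cal[2] <- 8
  cohort <- list(make_series(c(5, 6, 7, 8), calibration = cal),
                 make_series(c(9, 10), "P02"))
  ps <- pooled_summary(cohort)
  expect_identical(ps$n, 6L)
  expect_equal(ps$mean, mean(c(5, 6, 7, 8, 9, 10)))
  expect_identical(ps$n_calibration, 1L)
  expect_match(as.character(summary_to_json(ps)), '"n":6')
})
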