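mk_result <- function(pred, act) {
  forecast_result(15, pred, act, t0_utc + seq_along(pred) * 300)
}

test_that("mse is the exact mean squared error", {
  expect_identical(mse(mk_result(c(5, 6, 7), c(5, 6, 7))), 0)
  expect_equal(mse(mk_result(c(5, 6, 7), c(5, 5, 5))), 5 / 3, tolerance = 1e-15)

  # element-wise loop oracle on 50 random vectors
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    p <- runif(n, 3, 15); a <- runif(n, 3, 15)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (p[i] - a[i])^2
    expect_equal(mse(mk_result(p, a)), acc / n, tolerance = 1e-12)
    expect_gte(mse(mk_result(p, a)), 0)
  }
  expect_error(forecast_result(15, numeric(0), numeric(0), numeric(0)),
               class = "cgm_parameter_error")
})

test_that("persistence_forecast repeats the last observed value", {
  # constant series: perfect persistence
  wc <- make_windows(make_series(rep(7.5, 40)), window_spec(6, 3))
  expect_identical(mse(persistence_forecast(wc)), 0)

  # linear ramp with slope s per step at horizon H: MSE = (s*H)^2 exactly
  s <- 0.05; H <- 4L
  ramp <- 5 + s * (0:99)
  wr <- make_windows(make_series(ramp), window_spec(8, H))
  expect_equal(mse(persistence_forecast(wr)), (s * H)^2, tolerance = 1e-12)

  # total on arbitrary valid windows; refuses scaled input
  set.seed(2)
  for (rep in 1:10) {
    g <- runif(sample(12:60, 1), 4, 12)
    w <- tryCatch(make_windows(make_series(g), window_spec(6, 3)),
                  cgm_empty_dataset = function(e) NULL)
    if (!is.null(w)) expect_s3_class(persistence_forecast(w), "forecast_result")
  }
  sc <- fit_scaler(wr)
  expect_error(persistence_forecast(apply_scaler(wr, sc)), class = "cgm_contract_error")
})

test_that("qq_normality pairs Hazen quantiles and scores linearity", {
  n <- 200L
  theo <- qnorm((seq_len(n) - 0.5) / n)
  # residuals placed exactly on the normal quantiles -> near-perfect line
  act <- rep(8, n)
  qq <- qq_normality(mk_result(act + 2 + 0.5 * theo, act))
  expect_gte(qq$r, 0.999)
  expect_identical(qq$n, n)
  expect_equal(qq$theoretical_quantiles, theo)
  expect_true(!is.unsorted(qq$sample_quantiles))

  # heavy-tailed residuals score lower than Gaussian ones at the same n
  set.seed(31)
  e_norm <- rnorm(500)
  e_cauchy <- rcauchy(500)
  r_norm <- qq_normality(mk_result(rep(8, 500) + e_norm, rep(8, 500)))$r
  r_cauchy <- qq_normality(mk_result(rep(8, 500) + e_cauchy, rep(8, 500)))$r
  expect_lt(r_cauchy, r_norm)

  expect_error(qq_normality(mk_result(c(8, 8, 8), c(7, 7, 7))),
               class = "cgm_degenerate_input")
  expect_error(qq_normality(mk_result(c(8, 9), c(7, 7))),
               class = "cgm_insufficient_data")
})

test_that("evaluate_horizons produces a complete annotated grid", {
  cohort <- tiny_cohort(2, 2)
  tab <- evaluate_horizons(
    cohort, kinds = "transformer_lstm", horizons_min = 15,
    model_cfg = hybrid_config(d_model = 8, n_heads = 2, n_encoder_layers = 1,
                              ffn_width = 8, lstm_hidden = 8),
    train_cfg = train_config(lr = 3e-3, batch_size = 64, max_epochs = 2,
                             patience = Inf, max_train_windows = 256),
    max_test_windows = 200, seed = 1
  )
  expect_s3_class(tab, "comparison_table")
  expect_identical(dim(tab), c(1L, 1L))
  expect_true(is.finite(tab["transformer_lstm", "15min"]))
  expect_false(any(attr(tab, "failed")))
  md <- attr(tab, "metadata")
  expect_identical(md$seed, 1)
  expect_match(md$digest, "^[0-9a-f]{8}$")
  fc <- attr(tab, "forecasts")[["transformer_lstm_15"]]
  expect_s3_class(fc, "forecast_result")

  expect_error(evaluate_horizons(cohort, kinds = "rnn", horizons_min = 17),
               class = "cgm_parameter_error")
})

test_that("comparison tables round-trip through CSV and JSON", {
  tab <- as.data.frame(matrix(c(1.41, 2.34, 1.18, 1.70), 2, 2, byrow = TRUE,
                              dimnames = list(c("rnn", "transformer_lstm"),
                                              c("15min", "30min"))))
  class(tab) <- c("comparison_table", "data.frame")
  attr(tab, "metadata") <- list(seed = 1, digest = "deadbeef")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_comparison(tab, csv, js)
  back <- read_comparison(csv)
  expect_identical(rownames(back), rownames(tab))
  expect_equal(as.matrix(back), as.matrix(as.data.frame(tab)), tolerance = 1e-12)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$grid[["15min"]], c(1.41, 1.18))
  expect_identical(parsed$metadata$digest, "deadbeef")
})
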