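# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

t0_utc <- as.POSIXct("2022-03-01 00:00:00", tz = "UTC")

# regular 5-min series from a numeric vector
make_series <- function(values, patient_id = "P01", interval_min = 5,
                        start = t0_utc, calibration = NULL) {
  glucose_series(patient_id, start + (seq_along(values) - 1) * interval_min * 60,
                 values, calibration)
}

# small cohorts for end-to-end tests (memoised per session)
.fixture_env <- new.env()
tiny_cohort <- function(n_patients = 2, days = 4, seed = 1) {
  key <- sprintf("cohort_%d_%d_%d", n_patients, days, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(
      generator_config(n_patients = n_patients, days_per_patient = days),
      seed = seed
    )
  }
  .fixture_env[[key]]
}

# a small, fast model/training configuration used by the slow-path tests
fast_hybrid_cfg <- function(lookback = 12L) {
  hybrid_config(d_model = 16, n_heads = 2, n_encoder_layers = 2, ffn_width = 32,
                lstm_hidden = 32, lstm_layers = 1, dropout = 0.1,
                lookback = lookback)
}
fast_train_cfg <- function(seed = 1L, max_epochs = 12L, max_train_windows = 600) {
  train_config(lr = 3e-3, batch_size = 64, max_epochs = max_epochs, patience = 4,
               seed = seed, max_train_windows = max_train_windows)
}

# --- independent oracles ---

# streaming (Welford) moments, an independent route to mean/sd
welford <- function(x) {
  n <- 0; m <- 0; M2 <- 0
  for (v in x) {
    n <- n + 1
    d <- v - m
    m <- m + d / n
    M2 <- M2 + d * (v - m)
  }
  list(n = n, mean = m, sd = sqrt(M2 / (n - 1)))
}

# scalar element-by-element LSTM cell step (no matrix ops)
lstm_cell_oracle <- function(x_t, prev, p) {
  h <- p$hidden_size; d <- p$input_size
  z <- c(prev$h, x_t)
  gate <- function(W, b, act) {
    out <- numeric(h)
    for (j in seq_len(h)) {
      acc <- b[j]
      for (k in seq_len(h + d)) acc <- acc + W[j, k] * z[k]
      out[j] <- act(acc)
    }
    out
  }
  sig <- function(u) 1 / (1 + exp(-u))
  f <- gate(p$W_f, p$b_f, sig)
  i <- gate(p$W_i, p$b_i, sig)
  Ct <- gate(p$W_C, p$b_C, tanh)
  C <- numeric(h); hh <- numeric(h)
  O <- gate(p$W_O, p$b_O, sig)
  for (j in seq_len(h)) {
    C[j] <- f[j] * prev$C[j] + i[j] * Ct[j]
    hh[j] <- O[j] * tanh(C[j])
  }
  list(h = hh, C = C)
}

# exhaustive sliding-window enumeration over one glucose vector
enumerate_windows <- function(g, L, H) {
  out <- list()
  n <- length(g)
  i <- 1
  while (i + L + H - 1 <= n) {
    out[[length(out) + 1]] <- list(input = g[i:(i + L - 1)], target = g[i + L + H - 1])
    i <- i + 1
  }
  out
}

# finite-difference gradient of the batch MSE loss w.r.t. one parameter entry
fd_grad <- function(model, X, y, nm, k, eps = 1e-5) {
  p <- model$params[[nm]]
  v0 <- p$value[k]
  f <- function() {
    pr <- cgmforecast:::model_forward(model, X)$pred$value[, 1]
    mean((pr - y)^2)
  }
  p$value[k] <- v0 + eps; fp <- f()
  p$value[k] <- v0 - eps; fm <- f()
  p$value[k] <- v0
  (fp - fm) / (2 * eps)
}

# analytic gradients of the batch MSE loss for every parameter
analytic_grads <- function(model, X, y) {
  model <- cgmforecast:::clone_model(model)
  tape <- cgmforecast:::tape_new(TRUE)
  fw <- cgmforecast:::model_forward(model, X, train = FALSE, tape = tape)
  loss <- cgmforecast:::op_mse_loss(tape, fw$pred, matrix(y, ncol = 1))
  cgmforecast:::tape_backward(tape, loss)
  lapply(model$params, function(p) p$grad)
}
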