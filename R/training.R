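# Seeded minibatch training with early stopping. The loss is mean squared
# error on scaled targets (well conditioned); reported forecast errors are
# always converted back to mmol/L by the caller via the scaler.

#' Training configuration
#'
#' @param lr Learning rate (> 0; 0 is allowed and performs null updates,
#'   useful for diagnostics).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum epochs.
#' @param patience Early-stopping patience on validation loss; `Inf`
#'   disables early stopping.
#' @param val_frac Fraction in (0, 1) of the training windows held out, by
#'   chronological order, as the validation set.
#' @param seed Seed governing data order and dropout.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param max_train_windows Optional cap on training windows; when the
#'   training set is larger, it is thinned deterministically by an even
#'   stride. Keeps desk-scale benchmarks inside CPU-minute budgets.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, batch_size = 32L, max_epochs = 200L,
                         patience = 15L, val_frac = 0.2, seed = 1L,
                         optimizer = c("adam", "sgd"),
                         max_train_windows = Inf) {
  optimizer <- match.arg(optimizer)
  if (!is.numeric(lr) || lr < 0) stop_cgm("lr must be >= 0", class = "cgm_parameter_error")
  if (!is_count(max_epochs)) stop_cgm("max_epochs must be >= 1", class = "cgm_parameter_error")
  if (val_frac <= 0 || val_frac >= 1) stop_cgm("val_frac must be in (0, 1)", class = "cgm_parameter_error")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 val_frac = val_frac, seed = as.integer(seed),
                 optimizer = optimizer, max_train_windows = max_train_windows),
            class = "train_config")
}

adam_state_new <- function(params) {
  lapply(params, function(p) list(m = array(0, dim(p$value)),
                                  v = array(0, dim(p$value))))
}

optim_step <- function(params, state, cfg, t) {
  if (cfg$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (nm in names(params)) {
      p <- params[[nm]]
      g <- p$grad
      if (is.null(g)) next
      st <- state[[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      p$value <- p$value - cfg$lr * mhat / (sqrt(vhat) + eps)
      state[[nm]] <- st
    }
  } else {
    for (nm in names(params)) {
      p <- params[[nm]]
      if (!is.null(p$grad)) p$value <- p$value - cfg$lr * p$grad
    }
  }
  state
}

batch_loss <- function(model, inputs, targets, train = FALSE) {
  fw <- model_forward(model, inputs, train = train,
                      tape = if (train) tape_new(grad = TRUE) else NULL)
  loss <- op_mse_loss(fw$tape, fw$pred, matrix(targets, ncol = 1))
  list(loss = loss, tape = fw$tape)
}

eval_loss <- function(model, inputs, targets, chunk = 1024L) {
  n <- nrow(inputs)
  sse <- 0
  for (a in seq(1, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    p <- model_forward(model, inputs[a:b, , drop = FALSE])$pred$value[, 1]
    sse <- sse + sum((p - targets[a:b])^2)
  }
  sse / n
}

thin_windows <- function(w, max_n) {
  n <- nrow(w$inputs)
  if (!is.finite(max_n) || n <= max_n) return(w)
  windows_subset(w, round(seq(1, n, length.out = max_n)))
}

#' Train a forecaster on supervised windows
#'
#' Minimizes scaled-target MSE by minibatch gradient descent through the
#' package's autodiff engine. The chronologically last `val_frac` of the
#' windows is held out for validation; training stops once the validation
#' loss has not improved for `patience` epochs and the best-validation
#' parameters are restored. Fully reproducible given `cfg$seed` (shuffling,
#' dropout) and the model's init seed.
#'
#' @param model A `cgm_model` from [build_model()] (left unmodified; a
#'   trained copy is returned).
#' @param windows Scaled `supervised_windows`.
#' @param cfg A [train_config()].
#' @return `list(model = trained cgm_model, log = train_log)` where the log
#'   is a data.frame of per-epoch train/validation loss with attributes
#'   `best_epoch` and `stopped_early`.
#' @export
train <- function(model, windows, cfg = train_config()) {
  stopifnot(inherits(model, "cgm_model"), inherits(windows, "supervised_windows"))
  if (!windows$scaled) stop_cgm("train expects scaled windows", class = "cgm_contract_error")
  windows <- thin_windows(windows, cfg$max_train_windows)
  n <- nrow(windows$inputs)
  if (n < cfg$batch_size) {
    stop_cgm("n_windows (%d) < batch_size (%d)", n, cfg$batch_size,
             class = "cgm_parameter_error")
  }
  ord <- order(windows$target_times)
  n_val <- max(1L, floor(cfg$val_frac * n))
  n_tr <- n - n_val
  if (n_tr < 1) stop_cgm("validation split leaves no training windows", class = "cgm_parameter_error")
  tr_idx <- ord[seq_len(n_tr)]
  val_idx <- ord[(n_tr + 1):n]
  Xtr <- windows$inputs[tr_idx, , drop = FALSE]
  ytr <- windows$targets[tr_idx]
  Xval <- windows$inputs[val_idx, , drop = FALSE]
  yval <- windows$targets[val_idx]

  model <- clone_model(model)
  state <- adam_state_new(model$params)
  best_val <- Inf
  best_epoch <- 0L
  best_snapshot <- NULL
  stopped_early <- FALSE
  tl <- numeric(0); vl <- numeric(0)
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_tr)
      ep_loss <- 0
      n_batches <- 0L
      for (a in seq(1, n_tr, by = cfg$batch_size)) {
        b <- min(a + cfg$batch_size - 1L, n_tr)
        idx <- perm[a:b]
        for (p in model$params) p$grad <- NULL
        bl <- batch_loss(model, Xtr[idx, , drop = FALSE], ytr[idx], train = TRUE)
        lv <- bl$loss$value[1, 1]
        if (!is.finite(lv)) {
          stop_cgm("training diverged (non-finite loss) at epoch %d", epoch,
                   class = "cgm_divergence_error")
        }
        tape_backward(bl$tape, bl$loss)
        step <- step + 1L
        state <- optim_step(model$params, state, cfg, step)
        ep_loss <- ep_loss + lv * length(idx)
        n_batches <- n_batches + 1L
      }
      tl[epoch] <- ep_loss / n_tr
      vl[epoch] <- eval_loss(model, Xval, yval)
      if (vl[epoch] < best_val - 1e-12) {
        best_val <- vl[epoch]
        best_epoch <- epoch
        best_snapshot <- lapply(model$params, function(p) p$value)
      } else if (is.finite(cfg$patience) && epoch - best_epoch >= cfg$patience) {
        stopped_early <- TRUE
        break
      }
    }
  })
  if (!is.null(best_snapshot)) {
    for (nm in names(best_snapshot)) model$params[[nm]]$value <- best_snapshot[[nm]]
  }
  log <- data.frame(epoch = seq_along(tl), train_loss = tl, val_loss = vl)
  attr(log, "best_epoch") <- best_epoch
  attr(log, "stopped_early") <- stopped_early
  class(log) <- c("train_log", "data.frame")
  list(model = model, log = log)
}

#' Forecast supervised windows with a trained model
#'
#' Runs the evaluation-mode forward pass and converts predictions (and
#' targets, if the windows are scaled) back to mmol/L, pairing each
#' prediction `yhat(t | t - PH)` with its actual `y(t)` by target time.
#'
#' @param object A trained `cgm_model`.
#' @param windows `supervised_windows` sharing the model's lookback.
#' @param scaler The `cgm_scaler` used for the windows; required when they
#'   are scaled.
#' @param ... Unused.
#' @return A [forecast_result()].
#' @export
predict.cgm_model <- function(object, windows, scaler = NULL, ...) {
  stopifnot(inherits(windows, "supervised_windows"))
  if (windows$scaled && is.null(scaler)) scaler <- windows$scaler
  if (windows$scaled && is.null(scaler)) {
    stop_cgm("scaled windows need a scaler to invert predictions", class = "cgm_contract_error")
  }
  n <- nrow(windows$inputs)
  preds <- numeric(n)
  chunk <- 1024L
  for (a in seq(1, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    preds[a:b] <- model_forward(object, windows$inputs[a:b, , drop = FALSE])$pred$value[, 1]
  }
  actuals <- windows$targets
  if (windows$scaled) {
    preds <- invert_scaler(preds, scaler)
    actuals <- invert_scaler(actuals, scaler)
  }
  forecast_result(
    horizon_min = windows$spec$horizon_steps * windows$spec$interval_min,
    predictions = preds, actuals = actuals, target_times = windows$target_times
  )
}
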