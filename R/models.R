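# Forecaster architectures. The hybrid model embeds each scaled glucose
# sample, adds sinusoidal positional encoding, runs a (post-norm)
# Transformer encoder stack, then feeds the encoded sequence to two
# branches: a position-pooled summary of the encoder output and an LSTM
# over the encoder output whose final hidden state captures temporal
# structure. The branch features are concatenated and a linear head emits
# the scalar glucose forecast. Five recurrent baselines (rnn, gru, lstm,
# stacked_lstm, bilstm) share the embedding -> recurrent core ->
# final-state -> linear-head skeleton.

MODEL_KINDS <- c("rnn", "gru", "lstm", "stacked_lstm", "bilstm", "transformer_lstm")

#' Hybrid model configuration
#'
#' @param d_model Embedding width (must be divisible by `n_heads`, even).
#' @param n_heads Attention heads.
#' @param n_encoder_layers Transformer encoder blocks.
#' @param ffn_width Width of the position-wise feed-forward layer.
#' @param lstm_hidden Hidden size of the LSTM branch / recurrent baselines.
#' @param lstm_layers LSTM layers (2 are used by `stacked_lstm`).
#' @param dropout Dropout rate in `[0, 1)`, active only during training.
#' @param lookback Input window length L in samples.
#' @param pooling Transformer-branch pooling over positions: `"mean"` or
#'   `"last"`.
#' @return A `hybrid_config` list.
#' @export
hybrid_config <- function(d_model = 16L, n_heads = 2L, n_encoder_layers = 2L,
                          ffn_width = 32L, lstm_hidden = 32L, lstm_layers = 1L,
                          dropout = 0.1, lookback = 12L,
                          pooling = c("mean", "last")) {
  pooling <- match.arg(pooling)
  for (v in list(d_model, n_heads, n_encoder_layers, ffn_width, lstm_hidden,
                 lstm_layers, lookback)) {
    if (!is_count(v)) stop_cgm("all size fields must be positive integers",
                               class = "cgm_config_error")
  }
  if (d_model %% n_heads != 0) {
    stop_cgm("d_model (%d) must be divisible by n_heads (%d)", d_model, n_heads,
             class = "cgm_config_error")
  }
  if (d_model %% 2 != 0) stop_cgm("d_model must be even", class = "cgm_config_error")
  if (dropout < 0 || dropout >= 1) stop_cgm("dropout must be in [0, 1)", class = "cgm_config_error")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 ffn_width = as.integer(ffn_width),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers), dropout = dropout,
                 lookback = as.integer(lookback), pooling = pooling),
            class = "hybrid_config")
}

#' Sinusoidal positional encoding table
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))`, `PE[pos, 2i+1] = cos(same)`
#' (0-based indexing); all entries lie in `[-1, 1]`. Added to embeddings so
#' unmasked self-attention can use sequence order.
#'
#' @param L Number of positions (rows).
#' @param d_model Even embedding width (columns).
#' @return An `L x d_model` matrix.
#' @export
positional_encoding <- function(L, d_model) {
  if (!is_count(L)) stop_cgm("L must be a positive integer", class = "cgm_parameter_error")
  if (!is_count(d_model) || d_model %% 2 != 0) {
    stop_cgm("d_model must be a positive even integer", class = "cgm_parameter_error")
  }
  pos <- 0:(L - 1)
  pe <- matrix(0, L, d_model)
  for (j in seq_len(d_model)) {
    i <- (j - 1) %/% 2
    ang <- pos / 10000^(2 * i / d_model)
    pe[, j] <- if (j %% 2 == 1) sin(ang) else cos(ang)
  }
  pe
}

## ---- LSTM cell at the equation level ----

#' LSTM cell parameters (gate form)
#'
#' Weight matrices act on the concatenation `[h_{t-1}, x_t]`; one matrix and
#' bias per gate (forget, input, candidate, output), each of shape
#' `hidden_size x (hidden_size + input_size)`.
#'
#' @param hidden_size,input_size Dimensions.
#' @param init `"zeros"` or `"uniform"` (+-1/sqrt(fan_in), seeded).
#' @param seed Seed for `init = "uniform"`.
#' @return An `lstm_cell_params` list with `W_f, W_i, W_C, W_O`,
#'   `b_f, b_i, b_C, b_O`, `hidden_size`, `input_size`.
#' @export
lstm_cell_params <- function(hidden_size, input_size, init = c("zeros", "uniform"),
                             seed = 1L) {
  init <- match.arg(init)
  k <- hidden_size + input_size
  mk <- function() matrix(0, hidden_size, k)
  p <- list(W_f = mk(), W_i = mk(), W_C = mk(), W_O = mk(),
            b_f = numeric(hidden_size), b_i = numeric(hidden_size),
            b_C = numeric(hidden_size), b_O = numeric(hidden_size),
            hidden_size = as.integer(hidden_size), input_size = as.integer(input_size))
  if (init == "uniform") {
    s <- 1 / sqrt(k)
    p[1:4] <- with_seed(seed, lapply(1:4, function(i) {
      matrix(stats::runif(hidden_size * k, -s, s), hidden_size, k)
    }))
  }
  structure(p, class = "lstm_cell_params")
}

#' One LSTM cell step
#'
#' The canonical gated recurrence: with `z = [h_{t-1}, x_t]`,
#' `f_t = sigmoid(W_f z + b_f)`, `i_t = sigmoid(W_i z + b_i)`,
#' `C~_t = tanh(W_C z + b_C)`, `C_t = f_t * C_{t-1} + i_t * C~_t`,
#' `O_t = sigmoid(W_O z + b_O)`, `h_t = O_t * tanh(C_t)` (elementwise
#' products). `|h_t| < 1` always, since both factors are bounded by 1.
#'
#' @param x_t Input vector (length `input_size`).
#' @param prev Previous state `list(h, C)`; `NULL` means zeros.
#' @param params An [lstm_cell_params()].
#' @return `list(state = list(h, C), gates = list(f_t, i_t, O_t, C_tilde))`.
#' @export
lstm_cell_step <- function(x_t, prev = NULL, params) {
  stopifnot(inherits(params, "lstm_cell_params"))
  h <- params$hidden_size
  if (length(x_t) != params$input_size) {
    stop_cgm("x_t length %d != input_size %d", length(x_t), params$input_size,
             class = "cgm_parameter_error")
  }
  if (is.null(prev)) prev <- list(h = numeric(h), C = numeric(h))
  if (length(prev$h) != h || length(prev$C) != h) {
    stop_cgm("state length mismatch with hidden_size %d", h, class = "cgm_parameter_error")
  }
  z <- c(prev$h, x_t)
  sig <- function(u) 1 / (1 + exp(-u))
  f_t <- sig(as.vector(params$W_f %*% z) + params$b_f)
  i_t <- sig(as.vector(params$W_i %*% z) + params$b_i)
  C_tilde <- tanh(as.vector(params$W_C %*% z) + params$b_C)
  C_t <- f_t * prev$C + i_t * C_tilde
  O_t <- sig(as.vector(params$W_O %*% z) + params$b_O)
  h_t <- O_t * tanh(C_t)
  list(state = list(h = h_t, C = C_t),
       gates = list(f_t = f_t, i_t = i_t, O_t = O_t, C_tilde = C_tilde))
}

#' LSTM forward pass over a sequence
#'
#' Exact left fold of [lstm_cell_step()] over the rows of `seq`.
#'
#' @param seq A `T x input_size` matrix (one row per time step).
#' @param init Initial state `list(h, C)` or `NULL` for zeros.
#' @param params An [lstm_cell_params()].
#' @return A `T x hidden_size` matrix of hidden states `h_t`, with the final
#'   state attached as attribute `"state"`.
#' @export
lstm_forward <- function(seq, init = NULL, params) {
  seq <- as.matrix(seq)
  if (nrow(seq) == 0) stop_cgm("empty sequence", class = "cgm_parameter_error")
  st <- init
  H <- matrix(0, nrow(seq), params$hidden_size)
  for (t in seq_len(nrow(seq))) {
    res <- lstm_cell_step(seq[t, ], st, params)
    st <- res$state
    H[t, ] <- st$h
  }
  attr(H, "state") <- st
  H
}

## ---- parameter initialization and the trainable models ----

init_mat <- function(nr, nc, fan_in = nr) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# LSTM stack parameter block; fused gate layout [f | i | c | o] along columns
init_lstm_block <- function(P, prefix, input_size, hidden) {
  P[[paste0(prefix, "_wx")]] <- nd_param(init_mat(input_size, 4 * hidden))
  P[[paste0(prefix, "_wh")]] <- nd_param(init_mat(hidden, 4 * hidden))
  P[[paste0(prefix, "_b")]] <- nd_param(matrix(0, 1, 4 * hidden))
  P
}

#' Build a forecaster
#'
#' All six kinds share the skeleton: per-step linear embedding of the scaled
#' glucose value to `d_model`, a sequence core, a final feature vector and a
#' linear head to the scalar forecast. `transformer_lstm` is the hybrid
#' architecture; the rest are recurrent baselines (no positional encoding).
#' Initialization is uniform +-1/sqrt(fan_in) and deterministic given `seed`.
#'
#' @param kind One of `"rnn"`, `"gru"`, `"lstm"`, `"stacked_lstm"`,
#'   `"bilstm"`, `"transformer_lstm"`.
#' @param cfg A [hybrid_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `cgm_model`.
#' @export
build_model <- function(kind = MODEL_KINDS, cfg = hybrid_config(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "hybrid_config"))
  d <- cfg$d_model; h <- cfg$lstm_hidden
  P <- list()
  with_seed(seed, {
    P$emb_w <- nd_param(init_mat(1, d, fan_in = 1))
    P$emb_b <- nd_param(matrix(0, 1, d))
    if (kind == "transformer_lstm") {
      for (l in seq_len(cfg$n_encoder_layers)) {
        pre <- sprintf("enc%d_", l)
        for (nm in c("wq", "wk", "wv", "wo")) P[[paste0(pre, nm)]] <- nd_param(init_mat(d, d))
        for (nm in c("bq", "bk", "bv", "bo")) P[[paste0(pre, nm)]] <- nd_param(matrix(0, 1, d))
        P[[paste0(pre, "ln1_g")]] <- nd_param(matrix(1, 1, d))
        P[[paste0(pre, "ln1_b")]] <- nd_param(matrix(0, 1, d))
        P[[paste0(pre, "ffn_w1")]] <- nd_param(init_mat(d, cfg$ffn_width))
        P[[paste0(pre, "ffn_b1")]] <- nd_param(matrix(0, 1, cfg$ffn_width))
        P[[paste0(pre, "ffn_w2")]] <- nd_param(init_mat(cfg$ffn_width, d))
        P[[paste0(pre, "ffn_b2")]] <- nd_param(matrix(0, 1, d))
        P[[paste0(pre, "ln2_g")]] <- nd_param(matrix(1, 1, d))
        P[[paste0(pre, "ln2_b")]] <- nd_param(matrix(0, 1, d))
      }
      for (j in seq_len(cfg$lstm_layers)) {
        P <- init_lstm_block(P, paste0("lstm", j), if (j == 1) d else h, h)
      }
      P$head_w <- nd_param(init_mat(d + h, 1))
      P$head_b <- nd_param(matrix(0, 1, 1))
    } else if (kind == "rnn") {
      P$core_wx <- nd_param(init_mat(d, h))
      P$core_wh <- nd_param(init_mat(h, h))
      P$core_b <- nd_param(matrix(0, 1, h))
      P$head_w <- nd_param(init_mat(h, 1))
      P$head_b <- nd_param(matrix(0, 1, 1))
    } else if (kind == "gru") {
      P$core_wx <- nd_param(init_mat(d, 3 * h))
      P$core_wh <- nd_param(init_mat(h, 3 * h))
      P$core_b <- nd_param(matrix(0, 1, 3 * h))
      P$head_w <- nd_param(init_mat(h, 1))
      P$head_b <- nd_param(matrix(0, 1, 1))
    } else if (kind == "lstm") {
      P <- init_lstm_block(P, "lstm1", d, h)
      P$head_w <- nd_param(init_mat(h, 1))
      P$head_b <- nd_param(matrix(0, 1, 1))
    } else if (kind == "stacked_lstm") {
      P <- init_lstm_block(P, "lstm1", d, h)
      P <- init_lstm_block(P, "lstm2", h, h)
      P$head_w <- nd_param(init_mat(h, 1))
      P$head_b <- nd_param(matrix(0, 1, 1))
    } else if (kind == "bilstm") {
      P <- init_lstm_block(P, "lstm1", d, h)
      P <- init_lstm_block(P, "lstm1r", d, h)
      P$head_w <- nd_param(init_mat(2 * h, 1))
      P$head_b <- nd_param(matrix(0, 1, 1))
    }
  })
  structure(list(kind = kind, cfg = cfg, params = P, seed = as.integer(seed)),
            class = "cgm_model")
}

#' @export
print.cgm_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<cgm_model> kind=%s, L=%d, d_model=%d, lstm_hidden=%d, %d parameters\n",
              x$kind, x$cfg$lookback, x$cfg$d_model, x$cfg$lstm_hidden, np))
  invisible(x)
}

# deep copy: parameter values live in environments
clone_model <- function(model) {
  model$params <- lapply(model$params, function(p) nd_param(p$value))
  model
}

# fused-gate LSTM stack forward on the tape; xs is a list of B x d nodes
lstm_tape_forward <- function(tape, xs, wx, wh, b, hidden, B) {
  hn <- nd_const(matrix(0, B, hidden))
  Cn <- nd_const(matrix(0, B, hidden))
  hs <- vector("list", length(xs))
  i1 <- seq_len(hidden)
  for (t in seq_along(xs)) {
    G <- op_add(tape, op_add(tape, op_mm(tape, xs[[t]], wx), op_mm(tape, hn, wh)), b)
    f <- op_sigmoid(tape, op_cols(tape, G, i1))
    i <- op_sigmoid(tape, op_cols(tape, G, hidden + i1))
    ct <- op_tanh(tape, op_cols(tape, G, 2L * hidden + i1))
    o <- op_sigmoid(tape, op_cols(tape, G, 3L * hidden + i1))
    Cn <- op_add(tape, op_mul(tape, f, Cn), op_mul(tape, i, ct))
    hn <- op_mul(tape, o, op_tanh(tape, Cn))
    hs[[t]] <- hn
  }
  hs
}

# transformer encoder stack on the tape (post-norm blocks, unmasked MHA)
encoder_tape_forward <- function(tape, X, P, cfg, B, L, train) {
  for (l in seq_len(cfg$n_encoder_layers)) {
    pre <- sprintf("enc%d_", l)
    p <- function(nm) P[[paste0(pre, nm)]]
    Q <- op_add(tape, op_mm(tape, X, p("wq")), p("bq"))
    K <- op_add(tape, op_mm(tape, X, p("wk")), p("bk"))
    V <- op_add(tape, op_mm(tape, X, p("wv")), p("bv"))
    A <- op_attention(tape, Q, K, V, B, L, cfg$n_heads)
    A <- op_add(tape, op_mm(tape, A, p("wo")), p("bo"))
    A <- op_dropout(tape, A, cfg$dropout, train)
    X <- op_layernorm(tape, op_add(tape, X, A), p("ln1_g"), p("ln1_b"))
    Ff <- op_relu(tape, op_add(tape, op_mm(tape, X, p("ffn_w1")), p("ffn_b1")))
    Ff <- op_add(tape, op_mm(tape, Ff, p("ffn_w2")), p("ffn_b2"))
    Ff <- op_dropout(tape, Ff, cfg$dropout, train)
    X <- op_layernorm(tape, op_add(tape, X, Ff), p("ln2_g"), p("ln2_b"))
  }
  X
}

# Single forward implementation for every kind; X is a B x L matrix of
# scaled inputs. Returns the B x 1 prediction node (plus the tape used).
model_forward <- function(model, X, train = FALSE, tape = NULL,
                          add_positional = TRUE) {
  stopifnot(inherits(model, "cgm_model"))
  X <- as.matrix(X)
  cfg <- model$cfg
  L <- ncol(X)
  if (L != cfg$lookback) {
    stop_cgm("input window length %d != configured lookback %d", L, cfg$lookback,
             class = "cgm_parameter_error")
  }
  B <- nrow(X)
  if (is.null(tape)) tape <- tape_new(grad = FALSE)
  P <- model$params
  xcol <- nd_const(matrix(as.vector(t(X)), ncol = 1))  # window-major stacking
  E <- op_add(tape, op_mm(tape, xcol, P$emb_w), P$emb_b)
  step_rows <- function(t) (seq_len(B) - 1L) * L + t
  if (model$kind == "transformer_lstm") {
    if (add_positional) {
      pe <- positional_encoding(L, cfg$d_model)
      E <- op_add(tape, E, nd_const(pe[rep(seq_len(L), B), , drop = FALSE]))
    }
    E <- op_dropout(tape, E, cfg$dropout, train)
    Enc <- encoder_tape_forward(tape, E, P, cfg, B, L, train)
    pooled <- if (cfg$pooling == "mean") {
      op_pool_mean(tape, Enc, B, L)
    } else {
      op_rows(tape, Enc, step_rows(L))
    }
    xs <- lapply(seq_len(L), function(t) op_rows(tape, Enc, step_rows(t)))
    for (j in seq_len(cfg$lstm_layers)) {
      pre <- paste0("lstm", j)
      xs <- lstm_tape_forward(tape, xs, P[[paste0(pre, "_wx")]],
                              P[[paste0(pre, "_wh")]], P[[paste0(pre, "_b")]],
                              cfg$lstm_hidden, B)
    }
    feat <- op_concat_cols(tape, pooled, xs[[L]])
  } else {
    xs <- lapply(seq_len(L), function(t) op_rows(tape, E, step_rows(t)))
    h <- cfg$lstm_hidden
    if (model$kind == "rnn") {
      hn <- nd_const(matrix(0, B, h))
      for (t in seq_len(L)) {
        hn <- op_tanh(tape, op_add(tape, op_add(
          tape, op_mm(tape, xs[[t]], P$core_wx), op_mm(tape, hn, P$core_wh)
        ), P$core_b))
      }
      feat <- hn
    } else if (model$kind == "gru") {
      hn <- nd_const(matrix(0, B, h))
      i1 <- seq_len(h)
      wx_zr <- op_cols(tape, P$core_wx, c(i1, h + i1))
      wh_zr <- op_cols(tape, P$core_wh, c(i1, h + i1))
      b_zr <- op_cols(tape, P$core_b, c(i1, h + i1))
      wx_n <- op_cols(tape, P$core_wx, 2L * h + i1)
      wh_n <- op_cols(tape, P$core_wh, 2L * h + i1)
      b_n <- op_cols(tape, P$core_b, 2L * h + i1)
      ones <- nd_const(matrix(1, B, h))
      for (t in seq_len(L)) {
        G <- op_add(tape, op_add(tape, op_mm(tape, xs[[t]], wx_zr),
                                 op_mm(tape, hn, wh_zr)), b_zr)
        z <- op_sigmoid(tape, op_cols(tape, G, i1))
        r <- op_sigmoid(tape, op_cols(tape, G, h + i1))
        n_ <- op_tanh(tape, op_add(tape, op_add(
          tape, op_mm(tape, xs[[t]], wx_n),
          op_mul(tape, r, op_mm(tape, hn, wh_n))
        ), b_n))
        hn <- op_add(tape, op_mul(tape, z, hn),
                     op_mul(tape, op_sub(tape, ones, z), n_))
      }
      feat <- hn
    } else if (model$kind %in% c("lstm", "stacked_lstm")) {
      hs <- lstm_tape_forward(tape, xs, P$lstm1_wx, P$lstm1_wh, P$lstm1_b, h, B)
      if (model$kind == "stacked_lstm") {
        hs <- lstm_tape_forward(tape, hs, P$lstm2_wx, P$lstm2_wh, P$lstm2_b, h, B)
      }
      feat <- hs[[L]]
    } else { # bilstm
      fwd <- lstm_tape_forward(tape, xs, P$lstm1_wx, P$lstm1_wh, P$lstm1_b, h, B)
      bwd <- lstm_tape_forward(tape, rev(xs), P$lstm1r_wx, P$lstm1r_wh, P$lstm1r_b, h, B)
      feat <- op_concat_cols(tape, fwd[[L]], bwd[[L]])
    }
  }
  pred <- op_add(tape, op_mm(tape, feat, P$head_w), P$head_b)
  list(pred = pred, tape = tape)
}

#' Transformer encoder forward pass
#'
#' Applies `cfg$n_encoder_layers` post-norm blocks (unmasked multi-head
#' self-attention with residual + layer normalization, then a position-wise
#' feed-forward network with residual + layer normalization) to an already
#' embedded sequence. Positional encoding is the caller's responsibility;
#' without it the map is permutation-equivariant in the rows.
#'
#' @param embedded An `L x d_model` matrix (positional encoding already
#'   added if order should matter).
#' @param cfg A [hybrid_config()].
#' @param weights Named list of plain weight matrices using the
#'   `enc<l>_{wq,bq,wk,bk,wv,bv,wo,bo,ln1_g,ln1_b,ffn_w1,ffn_b1,ffn_w2,ffn_b2,ln2_g,ln2_b}`
#'   layout (see [encoder_weights()]).
#' @return An `L x d_model` matrix.
#' @export
transformer_encoder <- function(embedded, cfg, weights) {
  embedded <- as.matrix(embedded)
  if (ncol(embedded) != cfg$d_model) {
    stop_cgm("embedded width %d != d_model %d", ncol(embedded), cfg$d_model,
             class = "cgm_config_error")
  }
  tape <- tape_new(grad = FALSE)
  W <- lapply(weights, nd_const)
  out <- encoder_tape_forward(tape, nd_const(embedded), W, cfg,
                              B = 1L, L = nrow(embedded), train = FALSE)
  out$value
}

#' Extract a model's encoder weights as plain matrices
#' @param model A hybrid `cgm_model`.
#' @return Named list of matrices accepted by [transformer_encoder()].
#' @export
encoder_weights <- function(model) {
  stopifnot(inherits(model, "cgm_model"), model$kind == "transformer_lstm")
  nms <- grep("^enc", names(model$params), value = TRUE)
  lapply(stats::setNames(nms, nms), function(nm) model$params[[nm]]$value)
}

#' Hybrid forward pass for a single window
#'
#' Evaluation-mode (deterministic, dropout inactive) forward of the hybrid
#' Transformer-LSTM on one scaled input window: embedding + positional
#' encoding -> encoder stack -> concatenation of the pooled encoder summary
#' with the final LSTM hidden state -> linear head -> scalar forecast.
#'
#' @param window Numeric vector of length `model$cfg$lookback` (scaled units).
#' @param model A `cgm_model` of kind `"transformer_lstm"`.
#' @return A single numeric prediction (same scale as the inputs).
#' @export
hybrid_forward <- function(window, model) {
  stopifnot(inherits(model, "cgm_model"))
  if (model$kind != "transformer_lstm") {
    stop_cgm("hybrid_forward requires a transformer_lstm model", class = "cgm_parameter_error")
  }
  if (length(window) != model$cfg$lookback) {
    stop_cgm("window length %d != lookback %d", length(window), model$cfg$lookback,
             class = "cgm_parameter_error")
  }
  model_forward(model, matrix(window, 1), train = FALSE)$pred$value[1, 1]
}
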