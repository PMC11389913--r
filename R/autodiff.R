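# Minimal reverse-mode automatic differentiation on a linear tape.
#
# No deep-learning framework exists in the deployment environment, so the
# forecasters are trained by this engine. A node is an environment holding a
# numeric matrix `value`; recording ops push nodes with a backward closure
# onto the tape. The same op functions run with recording off for fast
# evaluation-mode forwards, so there is exactly one implementation of every
# forward pass. All values are dense double matrices.

tape_new <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$grad <- grad
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

# leaf holding a constant (no gradient tracked)
nd_const <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- as.matrix(value)
  nd$track <- FALSE
  nd
}

# leaf holding a trainable parameter (gradient accumulated into $grad)
nd_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- as.matrix(value)
  nd$grad <- NULL
  nd$track <- TRUE
  nd
}

nd_record <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  if (isTRUE(tape$grad)) {
    nd$grad <- NULL
    nd$track <- TRUE
    nd$backward <- backward
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  } else {
    nd$track <- FALSE
  }
  nd
}

nd_acc <- function(nd, g) {
  if (isTRUE(nd$track)) {
    nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  }
  invisible(NULL)
}

# Run the backward sweep from a scalar loss node.
tape_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- ops ----

op_mm <- function(tape, a, b) {
  v <- a$value %*% b$value
  nd_record(tape, v, function(g) {
    nd_acc(a, g %*% t(b$value))
    nd_acc(b, t(a$value) %*% g)
  })
}

# add; `b` may be a 1-row bias broadcast over the rows of `a`
op_add <- function(tape, a, b) {
  bias <- nrow(b$value) == 1L && nrow(a$value) > 1L
  v <- if (bias) sweep(a$value, 2, b$value[1, ], `+`) else a$value + b$value
  nd_record(tape, v, function(g) {
    nd_acc(a, g)
    nd_acc(b, if (bias) matrix(colSums(g), 1) else g)
  })
}

op_sub <- function(tape, a, b) {
  nd_record(tape, a$value - b$value, function(g) {
    nd_acc(a, g)
    nd_acc(b, -g)
  })
}

op_mul <- function(tape, a, b) {
  nd_record(tape, a$value * b$value, function(g) {
    nd_acc(a, g * b$value)
    nd_acc(b, g * a$value)
  })
}

op_scale <- function(tape, a, k) {
  nd_record(tape, a$value * k, function(g) nd_acc(a, g * k))
}

op_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  nd_record(tape, v, function(g) nd_acc(a, g * v * (1 - v)))
}

op_tanh <- function(tape, a) {
  v <- tanh(a$value)
  nd_record(tape, v, function(g) nd_acc(a, g * (1 - v * v)))
}

op_relu <- function(tape, a) {
  v <- a$value
  mask <- v > 0
  v[!mask] <- 0
  nd_record(tape, v, function(g) nd_acc(a, g * mask))
}

# inverted dropout; identity when not training
op_dropout <- function(tape, a, rate, train) {
  if (!train || rate <= 0) return(a)
  mask <- matrix(stats::runif(length(a$value)) >= rate, nrow(a$value)) / (1 - rate)
  nd_record(tape, a$value * mask, function(g) nd_acc(a, g * mask))
}

# row-wise layer normalization with learned gain/bias (1 x d each)
op_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(xhat, 2, gamma$value[1, ], `*`)
  v <- sweep(v, 2, beta$value[1, ], `+`)
  nd_record(tape, v, function(g) {
    dxhat <- sweep(g, 2, gamma$value[1, ], `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    nd_acc(a, inv * (dxhat - m1 - xhat * m2))
    nd_acc(gamma, matrix(colSums(g * xhat), 1))
    nd_acc(beta, matrix(colSums(g), 1))
  })
}

# fused multi-head scaled dot-product self-attention over B stacked windows
# of L rows each (window-major row layout); Q, K, V are (B*L) x d_model.
op_attention <- function(tape, Q, K, V, B, L, n_heads) {
  d <- ncol(Q$value)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, B * L, d)
  A_cache <- vector("list", B * n_heads)
  for (w in seq_len(B)) {
    rw <- ((w - 1L) * L + 1L):(w * L)
    for (h in seq_len(n_heads)) {
      ch <- ((h - 1L) * dh + 1L):(h * dh)
      Qw <- Q$value[rw, ch, drop = FALSE]
      Kw <- K$value[rw, ch, drop = FALSE]
      S <- (Qw %*% t(Kw)) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      A_cache[[(w - 1L) * n_heads + h]] <- A
      out[rw, ch] <- A %*% V$value[rw, ch, drop = FALSE]
    }
  }
  nd_record(tape, out, function(g) {
    dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
    for (w in seq_len(B)) {
      rw <- ((w - 1L) * L + 1L):(w * L)
      for (h in seq_len(n_heads)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        A <- A_cache[[(w - 1L) * n_heads + h]]
        gO <- g[rw, ch, drop = FALSE]
        Vw <- V$value[rw, ch, drop = FALSE]
        dV[rw, ch] <- t(A) %*% gO
        dA <- gO %*% t(Vw)
        dS <- A * (dA - rowSums(A * dA))
        dQ[rw, ch] <- (dS %*% K$value[rw, ch, drop = FALSE]) * scale
        dK[rw, ch] <- (t(dS) %*% Q$value[rw, ch, drop = FALSE]) * scale
      }
    }
    nd_acc(Q, dQ); nd_acc(K, dK); nd_acc(V, dV)
  })
}

op_rows <- function(tape, a, idx) {
  nr <- nrow(a$value)
  nd_record(tape, a$value[idx, , drop = FALSE], function(g) {
    z <- matrix(0, nr, ncol(g))
    z[idx, ] <- g
    nd_acc(a, z)
  })
}

op_cols <- function(tape, a, idx) {
  nc <- ncol(a$value)
  nd_record(tape, a$value[, idx, drop = FALSE], function(g) {
    z <- matrix(0, nrow(g), nc)
    z[, idx] <- g
    nd_acc(a, z)
  })
}

# mean over the L rows of each stacked window: (B*L) x d -> B x d
op_pool_mean <- function(tape, a, B, L) {
  grp <- rep(seq_len(B), each = L)
  v <- rowsum(a$value, grp) / L
  rownames(v) <- NULL
  nd_record(tape, v, function(g) nd_acc(a, g[grp, , drop = FALSE] / L))
}

op_concat_cols <- function(tape, a, b) {
  na <- ncol(a$value)
  nd_record(tape, cbind(a$value, b$value), function(g) {
    nd_acc(a, g[, seq_len(na), drop = FALSE])
    nd_acc(b, g[, (na + 1):ncol(g), drop = FALSE])
  })
}

# mean squared error against a constant target column
op_mse_loss <- function(tape, pred, target) {
  r <- pred$value - target
  n <- length(r)
  nd_record(tape, matrix(mean(r * r), 1, 1), function(g) {
    nd_acc(pred, (2 / n) * r * g[1, 1])
  })
}
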