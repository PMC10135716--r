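# A small reverse-mode automatic differentiation engine over R matrices.
# The network code builds a computational graph per forward pass; nodes are
# recorded on a tape in creation order, and the backward pass walks the tape
# in reverse, accumulating gradients into parent nodes. Leaf nodes (parameters
# and inputs) collect gradients too, which is what both the optimizer and the
# input-attribution methods consume.
#
# Every node value is a numeric matrix; reductions produce 1x1 matrices.

ad_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- vector("list", 256L)
  env$n <- 0L
  env
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node
}

ad_accum <- function(node, g) {
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
  invisible(NULL)
}

# Leaf: parameter or input. Gradients accumulate; nothing to backprop through.
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_backward <- function(tape, node, seed = 1) {
  node$grad <- matrix(seed, nrow(node$value), ncol(node$value))
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad %*% t(b$value))
    ad_accum(b, t(a$value) %*% nd$grad)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}

# Add a 1 x k bias row vector to every row of a.
ad_add_bias <- function(tape, a, bias) {
  ad_node(tape, sweep(a$value, 2, as.numeric(bias$value), "+"),
          list(a, bias), function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(bias, matrix(colSums(nd$grad), nrow = 1))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad * b$value)
    ad_accum(b, nd$grad * a$value)
  })
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(nd) {
    ad_accum(a, nd$grad * nd$value * (1 - nd$value))
  })
}

ad_tanh <- function(tape, a) {
  ad_node(tape, tanh(a$value), list(a), function(nd) {
    ad_accum(a, nd$grad * (1 - nd$value^2))
  })
}

ad_relu <- function(tape, a) {
  ad_node(tape, pmax(a$value, 0), list(a), function(nd) {
    ad_accum(a, nd$grad * (a$value > 0))
  })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(x) ncol(x$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  ad_node(tape, do.call(cbind, lapply(nodes, function(x) x$value)), nodes,
          function(nd) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[, idx] <- nd$grad
    ad_accum(a, g)
  })
}

# Row gather with zero-padding: idx0 entries of 0 yield zero rows; the
# backward pass scatters gradient rows back onto the source rows. Used by the
# im2col convolution lowering, whose index vectors never repeat a source row,
# so plain indexed assignment is a valid (and fast) scatter.
ad_gather_rows <- function(tape, a, idx0) {
  valid <- idx0 > 0L
  out <- matrix(0, length(idx0), ncol(a$value))
  out[valid, ] <- a$value[idx0[valid], , drop = FALSE]
  ad_node(tape, out, list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[idx0[valid], ] <- nd$grad[valid, , drop = FALSE]
    ad_accum(a, g)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(nd) {
    ad_accum(a, nd$grad * s)
  })
}

# Batch normalization over rows (per-column statistics). In training mode the
# batch statistics are used and the running statistics in `state` (an
# environment with mean/var) are updated in place; in inference mode the
# running statistics are used.
ad_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.97, eps = 1e-5) {
  g <- as.numeric(gamma$value)
  b <- as.numeric(beta$value)
  if (training) {
    n <- nrow(x$value)
    mu <- colMeans(x$value)
    xc <- sweep(x$value, 2, mu, "-")
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, istd, "*")
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- v
    } else {
      state$mean <- momentum * state$mean + (1 - momentum) * mu
      state$var <- momentum * state$var + (1 - momentum) * v
    }
    y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
    ad_node(tape, y, list(x, gamma, beta), function(nd) {
      dy <- nd$grad
      dgamma <- colSums(dy * xhat)
      dbeta <- colSums(dy)
      ad_accum(gamma, matrix(dgamma, nrow = 1))
      ad_accum(beta, matrix(dbeta, nrow = 1))
      t1 <- sweep(dy, 2, dbeta / n, "-")
      t2 <- sweep(xhat, 2, dgamma / n, "*")
      dx <- sweep(t1 - t2, 2, g * istd, "*")
      ad_accum(x, dx)
    })
  } else {
    mu <- if (is.null(state$mean)) rep(0, ncol(x$value)) else state$mean
    v <- if (is.null(state$var)) rep(1, ncol(x$value)) else state$var
    istd <- 1 / sqrt(v + eps)
    y <- sweep(sweep(sweep(x$value, 2, mu, "-"), 2, g * istd, "*"), 2, b, "+")
    ad_node(tape, y, list(x, gamma, beta), function(nd) {
      dy <- nd$grad
      xhat <- sweep(sweep(x$value, 2, mu, "-"), 2, istd, "*")
      ad_accum(gamma, matrix(colSums(dy * xhat), nrow = 1))
      ad_accum(beta, matrix(colSums(dy), nrow = 1))
      ad_accum(x, sweep(dy, 2, g * istd, "*"))
    })
  }
}

# Class-weighted binary cross-entropy from logits (numerically stable
# softplus form). y and w are plain numeric vectors. Value is a 1x1 matrix:
# mean over samples of w_i * bce_i.
ad_wbce_logits <- function(tape, z, y, w) {
  zv <- as.numeric(z$value)
  n <- length(zv)
  softplus <- ifelse(zv > 30, zv, log1p(exp(pmin(zv, 30))))
  loss <- sum(w * (softplus - y * zv)) / n
  ad_node(tape, matrix(loss, 1, 1), list(z), function(nd) {
    p <- 1 / (1 + exp(-zv))
    dz <- matrix(nd$grad[1, 1] * w * (p - y) / n, ncol = 1)
    ad_accum(z, dz)
  })
}

# Mean squared error over masked samples (mask 0/1 numeric vector); the mean
# is over the masked-in samples so negatives carry no regression signal.
ad_masked_mse <- function(tape, z, y, mask) {
  zv <- as.numeric(z$value)
  m <- max(sum(mask), 1)
  loss <- sum(mask * (zv - y)^2) / m
  ad_node(tape, matrix(loss, 1, 1), list(z), function(nd) {
    dz <- matrix(nd$grad[1, 1] * 2 * mask * (zv - y) / m, ncol = 1)
    ad_accum(z, dz)
  })
}

ad_value <- function(node) node$value

# Fused bidirectional-capable LSTM op. x is the (n*L) x C sample-major
# matrix (row (i-1)*L + t); the op runs the recurrence over positions
# (reversed when reverse = TRUE) and returns all hidden states as an
# n x (L*H) matrix, h_t in columns ((t-1)*H + 1):(t*H). The backward pass is
# hand-written backpropagation through time; gradients flow to x, the weight
# matrices (Wx: C x 4H, Wh: H x 4H) and the bias (1 x 4H). Gate order: input,
# forget, cell, output.
ad_lstm <- function(tape, x, Wx, Wh, b, n, L, reverse = FALSE) {
  H <- nrow(Wh$value)
  stopifnot(ncol(Wx$value) == 4 * H, ncol(Wh$value) == 4 * H,
            nrow(Wx$value) == ncol(x$value))
  Wxv <- Wx$value; Whv <- Wh$value; bv <- as.numeric(b$value)
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  hs <- matrix(0, n, H)
  cs <- matrix(0, n, H)
  cache <- vector("list", L)
  out <- matrix(0, n, L * H)
  for (t in steps) {
    rows <- (seq_len(n) - 1L) * L + t
    xt <- x$value[rows, , drop = FALSE]
    Z <- xt %*% Wxv + hs %*% Whv
    Z <- sweep(Z, 2, bv, "+")
    i_g <- 1 / (1 + exp(-Z[, 1:H, drop = FALSE]))
    f_g <- 1 / (1 + exp(-Z[, (H + 1):(2 * H), drop = FALSE]))
    g_g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- 1 / (1 + exp(-Z[, (3 * H + 1):(4 * H), drop = FALSE]))
    c_new <- f_g * cs + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    cache[[t]] <- list(xt = xt, h_prev = hs, c_prev = cs, i = i_g, f = f_g,
                       g = g_g, o = o_g, tc = tc)
    hs <- h_new
    cs <- c_new
    out[, ((t - 1) * H + 1):(t * H)] <- h_new
  }
  ad_node(tape, out, list(x, Wx, Wh, b), function(nd) {
    G <- nd$grad
    dX <- matrix(0, nrow(x$value), ncol(x$value))
    dWx <- matrix(0, nrow(Wxv), ncol(Wxv))
    dWh <- matrix(0, nrow(Whv), ncol(Whv))
    db <- numeric(4 * H)
    dh_next <- matrix(0, n, H)
    dc_next <- matrix(0, n, H)
    for (t in rev(steps)) {
      cc <- cache[[t]]
      dh <- G[, ((t - 1) * H + 1):(t * H), drop = FALSE] + dh_next
      dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
      do_ <- dh * cc$tc
      di <- dc * cc$g
      df <- dc * cc$c_prev
      dg <- dc * cc$i
      dZ <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do_ * cc$o * (1 - cc$o))
      rows <- (seq_len(n) - 1L) * L + t
      dX[rows, ] <- dZ %*% t(Wxv)
      dWx <- dWx + crossprod(cc$xt, dZ)
      dWh <- dWh + crossprod(cc$h_prev, dZ)
      db <- db + colSums(dZ)
      dh_next <- dZ %*% t(Whv)
      dc_next <- dc * cc$f
    }
    ad_accum(x, dX)
    ad_accum(Wx, dWx)
    ad_accum(Wh, dWh)
    ad_accum(b, matrix(db, nrow = 1))
  })
}

# Inverted dropout: in training mode each element is zeroed with probability
# `rate` and survivors are rescaled by 1/(1-rate); in inference mode the
# identity. The mask is drawn from the session RNG, so a seeded training run
# is reproducible.
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- (matrix(runif(length(a$value)), nrow(a$value)) >= rate) / (1 - rate)
  ad_node(tape, a$value * keep, list(a), function(nd) {
    ad_accum(a, nd$grad * keep)
  })
}
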