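# LSTM internals: vectorized single-layer LSTM with a dense softmax head,
# analytic backpropagation through time, and an Adam optimizer. Parameter
# layout follows the common two-bias convention (separate input-to-hidden and
# hidden-to-hidden bias vectors per gate stack), which is also the only
# convention under which the closed-form parameter count matches the
# published 6466 for the 16-input, 32-hidden, 2-class mesh-branch model.
# Gate order within the stacked 4h rows: input, forget, cell, output.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(d, h, c) {
  # uniform(-1/sqrt(h), 1/sqrt(h)) init, the de-facto standard for LSTM cells
  k <- 1 / sqrt(h)
  u <- function(n) runif(n, -k, k)
  list(W_ih = matrix(u(4L * h * d), 4L * h, d),
       W_hh = matrix(u(4L * h * h), 4L * h, h),
       b_ih = u(4L * h),
       b_hh = u(4L * h),
       W_out = matrix(u(h * c), h, c),
       b_out = u(c))
}

# Forward pass over a batch.
# x: array [B, T, d]; returns logits [B, c] and, if keep = TRUE, the cached
# activations needed for backprop.
lstm_forward <- function(params, x, keep = FALSE) {
  B <- dim(x)[1L]; T_ <- dim(x)[2L]
  h <- ncol(params$W_hh)
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  bias <- matrix(params$b_ih + params$b_hh, B, 4L * h, byrow = TRUE)
  cache <- if (keep) vector("list", T_) else NULL
  idx_i <- seq_len(h); idx_f <- h + idx_i; idx_g <- 2L * h + idx_i
  idx_o <- 3L * h + idx_i
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], B)
    A <- xt %*% t(params$W_ih) + H %*% t(params$W_hh) + bias
    gi <- sigmoid(A[, idx_i, drop = FALSE])
    gf <- sigmoid(A[, idx_f, drop = FALSE])
    gg <- tanh(A[, idx_g, drop = FALSE])
    go <- sigmoid(A[, idx_o, drop = FALSE])
    C_prev <- C
    C <- gf * C + gi * gg
    tC <- tanh(C)
    Hn <- go * tC
    if (keep)
      cache[[t]] <- list(x = xt, H_prev = H, C_prev = C_prev,
                         i = gi, f = gf, g = gg, o = go, tC = tC)
    H <- Hn
  }
  logits <- H %*% params$W_out +
    matrix(params$b_out, B, length(params$b_out), byrow = TRUE)
  list(logits = logits, H_last = H, cache = cache)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and gradients for a forward pass with cache.
# y: integer class index per batch row (1-based).
lstm_backward <- function(params, x, y, fwd) {
  B <- dim(x)[1L]; T_ <- dim(x)[2L]
  h <- ncol(params$W_hh)
  P <- softmax_rows(fwd$logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-300)))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  g <- list(W_ih = matrix(0, 4L * h, ncol(params$W_ih)),
            W_hh = matrix(0, 4L * h, h),
            b_ih = numeric(4L * h), b_hh = numeric(4L * h),
            W_out = t(fwd$H_last) %*% dZ,
            b_out = colSums(dZ))
  dH <- dZ %*% t(params$W_out)
  dC <- matrix(0, B, h)
  idx_i <- seq_len(h); idx_f <- h + idx_i; idx_g <- 2L * h + idx_i
  idx_o <- 3L * h + idx_i
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dO <- dH * cc$tC
    dC <- dC + dH * cc$o * (1 - cc$tC^2)
    dI <- dC * cc$g
    dF <- dC * cc$C_prev
    dG <- dC * cc$i
    dA <- cbind(dI * cc$i * (1 - cc$i),
                dF * cc$f * (1 - cc$f),
                dG * (1 - cc$g^2),
                dO * cc$o * (1 - cc$o))
    g$W_ih <- g$W_ih + t(dA) %*% cc$x
    g$W_hh <- g$W_hh + t(dA) %*% cc$H_prev
    db <- colSums(dA)
    g$b_ih <- g$b_ih + db
    g$b_hh <- g$b_hh + db
    dH <- dA %*% params$W_hh
    dC <- dC * cc$f
  }
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step (beta1 = 0.9, beta2 = 0.999, eps = 1e-8, the standard
# defaults; only the learning rate is a published hyperparameter).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
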