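# Neural-network primitives: dense, 1-D convolution (valid padding, im2col),
# ReLU, global max pooling, a 2-layer LSTM, and the Adam optimizer. All
# activations use a channels-first layout: conv inputs are (C, L, B) arrays,
# dense inputs (features, B) matrices. Forward functions return caches for
# the matching backward functions; backward correctness is checked against
# finite differences in the test suite.

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_bwd <- function(dy, cache) dy * cache$mask

dense_fwd <- function(x, W, b) {
  list(y = W %*% x + b, x = x)
}
dense_bwd <- function(dy, cache, W) {
  list(dW = tcrossprod(dy, cache$x), db = rowSums(dy), dx = crossprod(W, dy))
}

# x: (C, L, B); W: (F, C*k); b: length F. Valid padding, stride 1.
conv1d_fwd <- function(x, W, b, k) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  Lout <- L - k + 1L
  if (Lout < 1L) stop("conv1d: input length ", L, " shorter than kernel ", k)
  xm <- x; dim(xm) <- c(C * L, B)
  idx <- as.vector(outer(seq_len(C * k), (seq_len(Lout) - 1L) * C, "+"))
  cols <- xm[idx, , drop = FALSE]
  dim(cols) <- c(C * k, Lout * B)
  y <- W %*% cols + b
  dim(y) <- c(nrow(W), Lout, B)
  list(y = y, cols = cols, idx = idx, C = C, L = L, B = B, k = k, Lout = Lout)
}

conv1d_bwd <- function(dy, cache, W, need_dx = TRUE) {
  Fo <- nrow(W)
  dym <- dy; dim(dym) <- c(Fo, cache$Lout * cache$B)
  dW <- tcrossprod(dym, cache$cols)
  db <- rowSums(dym)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(W, dym)
    # adjoint of the im2col gather: scatter-add via rowsum over target rows
    dim(dcols) <- c(cache$C * cache$k * cache$Lout, cache$B)
    agg <- rowsum(dcols, cache$idx)
    dx <- matrix(0, cache$C * cache$L, cache$B)
    dx[as.integer(rownames(agg)), ] <- agg
    dim(dx) <- c(cache$C, cache$L, cache$B)
  }
  list(dW = dW, db = db, dx = dx)
}

# Global max pooling over the length axis: (F, L, B) -> (F, B).
maxpool_fwd <- function(x) {
  d <- dim(x)
  y <- apply(x, c(1, 3), max)
  arg <- apply(x, c(1, 3), which.max)
  dim(y) <- c(d[1], d[3]); dim(arg) <- c(d[1], d[3])
  list(y = y, arg = arg, dims = d)
}
maxpool_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, dim = d)
  fi <- rep(seq_len(d[1]), times = d[3])
  bi <- rep(seq_len(d[3]), each = d[1])
  dx[cbind(fi, as.vector(cache$arg), bi)] <- as.vector(dy)
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM layer run for all time steps. x: (In, L, B); Wx: (4H, In),
# Wh: (4H, H), b: 4H (gate order i, f, g, o). Returns hidden states
# h: (H, L, B) and per-step caches for BPTT.
lstm_fwd <- function(x, Wx, Wh, b) {
  d <- dim(x); L <- d[2]; B <- d[3]
  H <- ncol(Wh)
  h <- array(0, dim = c(H, L, B))
  hs <- matrix(0, H, B); cs <- matrix(0, H, B)
  gates <- vector("list", L); cells <- vector("list", L)
  prev_c <- vector("list", L)
  for (t in seq_len(L)) {
    z <- Wx %*% x[, t, ] + Wh %*% hs + b
    i <- sigmoid(z[seq_len(H), , drop = FALSE])
    f <- sigmoid(z[H + seq_len(H), , drop = FALSE])
    g <- tanh(z[2L * H + seq_len(H), , drop = FALSE])
    o <- sigmoid(z[3L * H + seq_len(H), , drop = FALSE])
    prev_c[[t]] <- cs
    cs <- f * cs + i * g
    hs <- o * tanh(cs)
    h[, t, ] <- hs
    gates[[t]] <- list(i = i, f = f, g = g, o = o)
    cells[[t]] <- cs
  }
  list(h = h, x = x, gates = gates, cells = cells, prev_c = prev_c,
       H = H, L = L, B = B)
}

# dh: (H, L, B) gradient w.r.t. every hidden state (zero where unused).
lstm_bwd <- function(dh, cache, Wx, Wh, need_dx = TRUE) {
  H <- cache$H; L <- cache$L; B <- cache$B
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H)
  dx <- if (need_dx) array(0, dim = dim(cache$x)) else NULL
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(L))) {
    g <- cache$gates[[t]]
    c_t <- cache$cells[[t]]; a <- tanh(c_t)
    dht <- dh[, t, ] + dh_next
    do <- dht * a
    dc <- dht * g$o * (1 - a^2) + dc_next
    di <- dc * g$g
    dg <- dc * g$i
    df <- dc * cache$prev_c[[t]]
    dc_next <- dc * g$f
    dz <- rbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                dg * (1 - g$g^2),
                do * g$o * (1 - g$o))
    h_prev <- if (t > 1L) matrix(cache$h[, t - 1L, ], ncol = B) else
      matrix(0, H, B)
    dWx <- dWx + tcrossprod(dz, matrix(cache$x[, t, ], ncol = B))
    dWh <- dWh + tcrossprod(dz, h_prev)
    db <- db + rowSums(dz)
    dh_next <- crossprod(Wh, dz)
    if (need_dx) dx[, t, ] <- crossprod(Wx, dz)
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

# ---- parameter initialisation and Adam -------------------------------------

glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nout * nin, -lim, lim), nout, nin)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    new <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.null(dim(params[[nm]]))) new <- as.numeric(new)
    params[[nm]] <- new
  }
  list(params = params, state = state)
}
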