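# Dense and LSTM building blocks with hand-written backward passes.
#
# No automatic differentiation is used anywhere in the package: each block
# returns a forward cache and exposes a backward function that consumes the
# gradient of the loss w.r.t. its output. Correctness is pinned down by a
# finite-difference gradient check in the test suite.

glorot_mat <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -a, a), n_in, n_out)
}

# ---- multilayer perceptron: tanh hidden layers, linear output --------------

init_mlp <- function(widths) {
  L <- length(widths) - 1L
  list(
    W = lapply(seq_len(L), function(l) glorot_mat(widths[l], widths[l + 1L])),
    b = lapply(seq_len(L), function(l) numeric(widths[l + 1L]))
  )
}

# X: n x d_in matrix. Returns list(out, cache).
mlp_forward <- function(p, X) {
  L <- length(p$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% p$W[[l]]
    Z <- sweep(Z, 2L, p$b[[l]], `+`)
    acts[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  list(out = acts[[L + 1L]], cache = acts)
}

# d_out: gradient w.r.t. output (n x d_out). Returns list(grads, dX).
mlp_backward <- function(p, cache, d_out) {
  L <- length(p$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dZ <- d_out
  for (l in rev(seq_len(L))) {
    A_prev <- cache[[l]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(p$W[[l]])
    if (l > 1L) dZ <- dA * (1 - cache[[l]]^2) else dX <- dA
  }
  list(grads = list(W = gW, b = gb), dX = dX)
}

# ---- single-layer LSTM over left-aligned padded batches --------------------
# Gate order in the stacked weight matrices: input, forget, cell, output.

init_lstm <- function(d_in, d_hidden) {
  b <- numeric(4L * d_hidden)
  b[(d_hidden + 1L):(2L * d_hidden)] <- 1 # forget-gate bias, standard init
  list(
    Wx = glorot_mat(d_in, 4L * d_hidden),
    Wh = glorot_mat(d_hidden, 4L * d_hidden),
    b = b
  )
}

# xs: list over time steps of n x d_in matrices; mask: n x T logical
# (TRUE where the step is a real event). Padded steps carry the previous
# hidden/cell state through unchanged so gradients flow only along real steps.
lstm_forward <- function(p, xs, mask) {
  Tn <- length(xs)
  n <- nrow(xs[[1L]])
  q <- nrow(p$Wh)
  h <- matrix(0, n, q)
  cc <- matrix(0, n, q)
  steps <- vector("list", Tn)
  hs <- vector("list", Tn)
  idx_i <- 1L:q
  idx_f <- (q + 1L):(2L * q)
  idx_g <- (2L * q + 1L):(3L * q)
  idx_o <- (3L * q + 1L):(4L * q)
  for (t in seq_len(Tn)) {
    m <- mask[, t]
    Z <- xs[[t]] %*% p$Wx + h %*% p$Wh
    Z <- sweep(Z, 2L, p$b, `+`)
    gi <- sigmoid(Z[, idx_i, drop = FALSE])
    gf <- sigmoid(Z[, idx_f, drop = FALSE])
    gg <- tanh(Z[, idx_g, drop = FALSE])
    go <- sigmoid(Z[, idx_o, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    steps[[t]] <- list(
      x = xs[[t]], h_prev = h, c_prev = cc,
      gi = gi, gf = gf, gg = gg, go = go, c_new = c_new, tc = tc, m = m
    )
    h <- m * h_new + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
    hs[[t]] <- h
  }
  list(hs = hs, cache = steps)
}

# d_hs: list over time steps of gradients w.r.t. the emitted hidden states.
lstm_backward <- function(p, cache, d_hs) {
  Tn <- length(cache)
  n <- nrow(d_hs[[1L]])
  q <- nrow(p$Wh)
  gWx <- p$Wx * 0
  gWh <- p$Wh * 0
  gb <- p$b * 0
  dh_next <- matrix(0, n, q)
  dc_next <- matrix(0, n, q)
  for (t in rev(seq_len(Tn))) {
    st <- cache[[t]]
    m <- st$m
    dh <- dh_next + d_hs[[t]]
    # carry-through at padded rows
    dh_valid <- m * dh
    dc_valid <- m * dc_next
    d_go <- dh_valid * st$tc
    dc <- dc_valid + dh_valid * st$go * (1 - st$tc^2)
    d_gi <- dc * st$gg
    d_gf <- dc * st$c_prev
    d_gg <- dc * st$gi
    dZ <- cbind(
      d_gi * st$gi * (1 - st$gi),
      d_gf * st$gf * (1 - st$gf),
      d_gg * (1 - st$gg^2),
      d_go * st$go * (1 - st$go)
    )
    gWx <- gWx + crossprod(st$x, dZ)
    gWh <- gWh + crossprod(st$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh_next <- dZ %*% t(p$Wh) + (1 - m) * dh
    dc_next <- st$gf * dc + (1 - m) * dc_next
    cache[[t]]$dx <- dZ %*% t(p$Wx)
  }
  list(
    grads = list(Wx = gWx, Wh = gWh, b = gb),
    dxs = lapply(cache, `[[`, "dx")
  )
}

# ---- AdamW (decoupled weight decay) ----------------------------------------

adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(
    function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
    state$m, state$v
  )
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0) {
    params <- tree_map(function(p) p - lr * weight_decay * p, params)
  }
  list(params = params, state = state)
}
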