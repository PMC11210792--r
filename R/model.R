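# The multi-task attention network.
#
# Per event kind (clinical measures, medications, patient-reported outcomes):
# an MLP encoder maps each event's features to a q-dimensional embedding; a
# single-layer LSTM processes the embeddings in time order; a local attention
# mechanism (trainable query vector, unscaled dot-product scores, softmax)
# aggregates the LSTM outputs into the event-history vector H(ev).
# A global attention mechanism (same construction) mixes the H(ev) and the
# demographics embedding into the patient representation P; concatenating the
# standardised time-to-prediction t gives the latent representation R = [P, t]
# that feeds two independent MLP prediction heads (DAS28, ASDAS) and is
# reused post hoc for patient similarity.

SCORE_KINDS <- c("das28", "asdas")

#' Network architecture configuration
#'
#' @param q Embedding size shared by every event kind and the demographics
#'   encoder (the matching-size requirement for the global mixture); the LSTM
#'   hidden size equals `q` so event histories and demographics live in the
#'   same space. The latent representation has length `q + 1`.
#' @param encoder_hidden Integer vector of hidden-layer widths of the MLP
#'   encoders (tanh activations, linear output).
#' @param head_hidden Hidden-layer widths of the two prediction heads.
#' @param dropout Dropout probability applied to the latent representation
#'   during training (0 disables it).
#' @return An object of class `dasnet_config`.
#' @export
dasnet_config <- function(q = 12L, encoder_hidden = c(16L, 16L),
                          head_hidden = c(16L, 16L), dropout = 0) {
  assert_positive(q, "q")
  stopifnot(all(encoder_hidden > 0), all(head_hidden > 0),
            dropout >= 0, dropout < 1)
  structure(
    list(q = as.integer(q), encoder_hidden = as.integer(encoder_hidden),
         head_hidden = as.integer(head_hidden), dropout = dropout,
         r = as.integer(q) + 1L),
    class = "dasnet_config"
  )
}

# initialise the full parameter tree for given per-kind input dimensions
init_dasnet_params <- function(config, input_dims) {
  q <- config$q
  kinds <- setdiff(names(input_dims), "dem")
  params <- list(enc = list(), lstm = list(), attn_u = list(), null = list())
  for (kd in kinds) {
    params$enc[[kd]] <- init_mlp(c(input_dims[[kd]], config$encoder_hidden, q))
    params$lstm[[kd]] <- init_lstm(q, q)
    params$attn_u[[kd]] <- rnorm(q) / sqrt(q)
    params$null[[kd]] <- rnorm(q) / sqrt(q)
  }
  params$enc_dem <- init_mlp(c(input_dims[["dem"]], config$encoder_hidden, q))
  params$glob_u <- rnorm(q) / sqrt(q)
  for (s in SCORE_KINDS) {
    params$head[[s]] <- init_mlp(c(config$r, config$head_hidden, 1L))
  }
  params
}

# ---- batched forward pass ---------------------------------------------------
# batch: output of make_batch(). Returns predictions, representations,
# attention records and (when train = TRUE or backward is needed) the cache.

dasnet_batch_forward <- function(params, batch, config, train = FALSE,
                                 dropout_mask = NULL) {
  q <- config$q
  kinds <- names(params$enc)
  N <- length(batch$t)
  comps <- list()
  locals <- list()
  caches <- list()

  for (kd in kinds) {
    bk <- batch$kinds[[kd]]
    n <- bk$n
    if (is.null(bk$X) || all(n == 0L)) {
      comps[[kd]] <- matrix(params$null[[kd]], N, q, byrow = TRUE)
      locals[[kd]] <- NULL
      caches[[kd]] <- list(all_empty = TRUE, n = n)
      next
    }
    Tn <- ncol(bk$idx)
    encf <- mlp_forward(params$enc[[kd]], bk$X)
    E <- encf$out
    xs <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      xt <- matrix(0, N, q)
      sel <- bk$idx[, t] > 0L
      if (any(sel)) xt[sel, ] <- E[bk$idx[sel, t], , drop = FALSE]
      xs[[t]] <- xt
    }
    mask <- sweep(matrix(seq_len(Tn), N, Tn, byrow = TRUE), 1L, n, `<=`)
    lf <- lstm_forward(params$lstm[[kd]], xs, mask)
    S <- vapply(lf$hs, function(h) as.numeric(h %*% params$attn_u[[kd]]),
                numeric(N))
    S <- matrix(S, N, Tn)
    a <- softmax_rows(S, mask)
    H <- matrix(0, N, q)
    for (t in seq_len(Tn)) H <- H + a[, t] * lf$hs[[t]]
    empty <- n == 0L
    if (any(empty)) {
      H[empty, ] <- matrix(params$null[[kd]], sum(empty), q, byrow = TRUE)
    }
    comps[[kd]] <- H
    aw <- a
    aw[!mask] <- NA_real_
    locals[[kd]] <- aw
    caches[[kd]] <- list(
      all_empty = FALSE, enc = encf$cache, lstm = lf, a = a, mask = mask,
      idx = bk$idx, n = n, empty = empty
    )
  }

  demf <- mlp_forward(params$enc_dem, batch$dem)
  comps$dem <- demf$out

  comp_names <- c(kinds, "dem")
  G <- vapply(comp_names, function(k) as.numeric(comps[[k]] %*% params$glob_u),
              numeric(N))
  G <- matrix(G, N, length(comp_names), dimnames = list(NULL, comp_names))
  A <- softmax_rows(G)
  P <- matrix(0, N, q)
  for (k in seq_along(comp_names)) P <- P + A[, k] * comps[[comp_names[k]]]
  R <- cbind(P, batch$t)

  R_in <- R
  if (train && config$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        (runif(N * ncol(R)) >= config$dropout) / (1 - config$dropout),
        N, ncol(R)
      )
    }
    R_in <- R * dropout_mask
  }

  heads <- list()
  pred <- numeric(N)
  for (s in SCORE_KINDS) {
    hf <- mlp_forward(params$head[[s]], R_in)
    heads[[s]] <- hf
    sel <- batch$score_kind == s
    pred[sel] <- hf$out[sel, 1L]
  }

  list(
    pred = pred, R = R, global = A, local = locals,
    cache = list(
      kinds = caches, demf = demf, comps = comps, comp_names = comp_names,
      A = A, heads = heads, batch = batch, dropout_mask = dropout_mask,
      R_in = R_in
    )
  )
}

# d_pred: gradient of the loss w.r.t. each instance's used prediction.
dasnet_batch_backward <- function(params, fwd, d_pred, config) {
  cache <- fwd$cache
  batch <- cache$batch
  q <- config$q
  N <- length(d_pred)
  grads <- tree_zeros_like(params)

  dR <- matrix(0, N, q + 1L)
  for (s in SCORE_KINDS) {
    sel <- batch$score_kind == s
    d_out <- matrix(0, N, 1L)
    d_out[sel, 1L] <- d_pred[sel]
    hb <- mlp_backward(params$head[[s]], cache$heads[[s]]$cache, d_out)
    grads$head[[s]] <- hb$grads
    dR <- dR + hb$dX
  }
  if (!is.null(cache$dropout_mask)) dR <- dR * cache$dropout_mask

  dP <- dR[, seq_len(q), drop = FALSE]
  comp_names <- cache$comp_names
  A <- cache$A
  K <- length(comp_names)
  dA <- matrix(0, N, K)
  dC <- vector("list", K)
  names(dC) <- comp_names
  for (k in seq_len(K)) {
    Ck <- cache$comps[[comp_names[k]]]
    dA[, k] <- rowSums(dP * Ck)
    dC[[k]] <- A[, k] * dP
  }
  dG <- A * (dA - rowSums(A * dA))
  gu <- numeric(q)
  for (k in seq_len(K)) {
    Ck <- cache$comps[[comp_names[k]]]
    gu <- gu + colSums(Ck * dG[, k])
    dC[[k]] <- dC[[k]] + outer(dG[, k], params$glob_u)
  }
  grads$glob_u <- gu

  demb <- mlp_backward(params$enc_dem, cache$demf$cache, dC$dem)
  grads$enc_dem <- demb$grads

  for (kd in names(params$enc)) {
    kc <- cache$kinds[[kd]]
    dH <- dC[[kd]]
    if (kc$all_empty) {
      grads$null[[kd]] <- colSums(dH)
      next
    }
    if (any(kc$empty)) {
      grads$null[[kd]] <- colSums(dH[kc$empty, , drop = FALSE])
      dH[kc$empty, ] <- 0
    }
    hs <- kc$lstm$hs
    Tn <- length(hs)
    a <- kc$a
    da <- matrix(0, N, Tn)
    d_hs <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      da[, t] <- rowSums(dH * hs[[t]])
      d_hs[[t]] <- a[, t] * dH
    }
    dS <- a * (da - rowSums(a * da))
    u <- params$attn_u[[kd]]
    du <- numeric(q)
    for (t in seq_len(Tn)) {
      du <- du + colSums(hs[[t]] * dS[, t])
      d_hs[[t]] <- d_hs[[t]] + outer(dS[, t], u)
    }
    grads$attn_u[[kd]] <- du
    lb <- lstm_backward(params$lstm[[kd]], kc$lstm$cache, d_hs)
    grads$lstm[[kd]] <- lb$grads
    dE <- matrix(0, sum(kc$n), q)
    for (t in seq_len(Tn)) {
      sel <- kc$idx[, t] > 0L
      if (any(sel)) {
        dE[kc$idx[sel, t], ] <- dE[kc$idx[sel, t], , drop = FALSE] +
          lb$dxs[[t]][sel, , drop = FALSE]
      }
    }
    eb <- mlp_backward(params$enc[[kd]], kc$enc, dE)
    grads$enc[[kd]] <- eb$grads
  }
  grads
}

# ---- exported stage operations ---------------------------------------------

#' Encode event features into embeddings
#'
#' Applies the MLP encoder of one event kind to a matrix of standardised
#' event features, preserving row (time) order.
#'
#' @param params A DAS network parameter set (e.g. `fit$params`).
#' @param X Numeric matrix, one row per event.
#' @param kind One of the model's event kinds (`"cm"`, `"med"`, `"prom"`) or
#'   `"dem"` for the demographics encoder.
#' @return Matrix of embeddings, one row per input row.
#' @export
encode_events <- function(params, X, kind) {
  enc <- if (identical(kind, "dem")) params$enc_dem else params$enc[[kind]]
  if (is.null(enc)) abort(sprintf("Unknown event kind '%s'.", kind))
  if (ncol(X) != nrow(enc$W[[1L]])) {
    abort(sprintf("Feature length %d does not match encoder input %d.",
                  ncol(X), nrow(enc$W[[1L]])))
  }
  mlp_forward(enc, X)$out
}

#' Aggregate an embedding sequence into an event-history vector
#'
#' Runs the kind's LSTM over the time-ordered embeddings, scores each output
#' with the trainable query vector, normalises the scores with a softmax and
#' returns the attention-weighted sum of the LSTM outputs.
#'
#' @param params A parameter set.
#' @param embeddings Matrix of time-ordered embeddings (rows are events).
#' @param kind Event kind.
#' @return List with `H` (aggregated history vector), `weights` (local
#'   attention weights, summing to 1) and `outputs` (LSTM output matrix).
#' @export
aggregate_event_history <- function(params, embeddings, kind) {
  n <- nrow(embeddings)
  if (n == 0L) abort("Cannot aggregate an empty embedding sequence.")
  xs <- lapply(seq_len(n), function(i) embeddings[i, , drop = FALSE])
  lf <- lstm_forward(params$lstm[[kind]], xs, matrix(TRUE, 1L, n))
  outs <- do.call(rbind, lf$hs)
  s <- as.numeric(outs %*% params$attn_u[[kind]])
  w <- as.numeric(softmax_rows(matrix(s, 1L)))
  list(H = as.numeric(crossprod(outs, w)), weights = w, outputs = outs)
}

#' Build the latent patient representation
#'
#' Mixes the aggregated event histories and the demographics embedding with
#' content-based global attention and concatenates the time-to-prediction.
#'
#' @param params A parameter set.
#' @param H Named list of aggregated history vectors (one per event kind;
#'   `NULL` entries are replaced by the kind's learned null vector).
#' @param e_dem Demographics embedding vector.
#' @param t Standardised time-to-prediction (scalar).
#' @return List with `R` (latent representation `[P, t]`), `P`, and
#'   `global` (named global attention weights over the kinds and `dem`).
#' @export
build_representation <- function(params, H, e_dem, t) {
  kinds <- names(params$enc)
  comps <- lapply(kinds, function(kd) H[[kd]] %||% params$null[[kd]])
  names(comps) <- kinds
  comps$dem <- e_dem
  scores <- vapply(comps, function(v) sum(v * params$glob_u), numeric(1))
  w <- as.numeric(softmax_rows(matrix(scores, 1L)))
  names(w) <- names(comps)
  P <- Reduce(`+`, Map(`*`, comps, w))
  list(R = c(P, t), P = P, global = w)
}

#' Predict both disease activity scores from a representation
#'
#' @param params A parameter set.
#' @param R Latent representation vector (or matrix, one row per instance).
#' @return Tibble with columns `das28` and `asdas` (one row per input row);
#'   the two heads are independent networks.
#' @export
predict_scores <- function(params, R) {
  if (is.null(dim(R))) R <- matrix(R, nrow = 1L)
  tibble(
    das28 = mlp_forward(params$head$das28, R)$out[, 1L],
    asdas = mlp_forward(params$head$asdas, R)$out[, 1L]
  )
}
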