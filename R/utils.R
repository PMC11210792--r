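# internal numeric helpers shared by the model, training and similarity code

# row-wise softmax with an optional logical mask (FALSE entries get weight 0).
# rows whose mask is entirely FALSE return all-zero weights.
softmax_rows <- function(scores, mask = NULL) {
  if (!is.null(mask)) scores[!mask] <- -Inf
  m <- apply(scores, 1L, max)
  m[!is.finite(m)] <- 0
  e <- exp(scores - m)
  e[!is.finite(e)] <- 0
  s <- rowSums(e)
  out <- e / ifelse(s > 0, s, 1)
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter trees -------------------------------------------------------
# model parameters are nested lists with numeric (matrix/vector) leaves.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(el) tree_map(f, el)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zeros_like <- function(x) tree_map(function(v) v * 0, x)

tree_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sumsq, numeric(1))) else sum(x^2)
}

tree_scale <- function(x, a) tree_map(function(v) v * a, x)

tree_add <- function(x, y) tree_map2(`+`, x, y)

tree_n_params <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_n_params, numeric(1))) else length(x)
}

# clip the global gradient norm in place (returns the clipped tree)
tree_clip_global_norm <- function(g, max_norm) {
  nrm <- sqrt(tree_sumsq(g))
  if (is.finite(max_norm) && nrm > max_norm && nrm > 0) {
    g <- tree_scale(g, max_norm / nrm)
  }
  g
}

assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", what))
  }
  invisible(x)
}

assert_fraction <- function(x, what, closed_zero = TRUE) {
  lo_ok <- if (closed_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || x >= 1) {
    abort(sprintf("`%s` must be a single number in [0, 1).", what))
  }
  invisible(x)
}
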