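# L1 k-nearest-neighbour retrieval over latent representations, the k-NN
# regression model, its raw-feature and random baselines, and the case-based
# feature-importance statistics (average absolute distance for continuous
# features, prior vs adjusted category probabilities for categorical ones).

#' Build an embedding index for similarity retrieval
#'
#' Computes the latent representation of every instance of the training and
#' test patients, together with the feature context: the last available raw
#' (unstandardised) value of each feature under the eligibility cutoff at
#' the time of the embedding.
#'
#' @param fit A fitted `dasnet`.
#' @param registry The registry the fit was trained on.
#' @param split Split tibble from [stratified_split()].
#' @param space `"latent"` (the network's representations) or `"raw"`
#'   (standardised last-value feature vectors — the raw-data k-NN baseline
#'   space).
#' @return An object of class `das_embedding_index`: tibbles `train`/`test`
#'   (instance keys and targets), matrices `R_train`/`R_test`, and feature
#'   context tibbles `context_train`/`context_test`.
#' @export
build_embedding_index <- function(fit, registry, split,
                                  space = c("latent", "raw")) {
  space <- match.arg(space)
  train_ids <- split$patient_id[split$split == "train"]
  test_ids <- split$patient_id[split$split == "test"]

  part <- function(ids) {
    instances <- filter(build_instances(registry, fit$lag_days),
                        !is.na(.data$y), .data$patient_id %in% ids) |>
      arrange(.data$patient_id, .data$target_index)
    if (space == "latent") {
      emb <- dasnet_embed(fit, registry, ids) |>
        arrange(.data$patient_id, .data$target_index)
      R <- as.matrix(select(emb, dplyr::starts_with("R")))
      keys <- select(emb, -dplyr::starts_with("R"))
    } else {
      lv <- build_last_value_features(registry, instances, fit$std,
                                      fit$t_stats, fit$lag_days)
      R <- lv$X
      keys <- tibble(
        patient_id = instances$patient_id,
        target_index = instances$target_index,
        score_kind = instances$score_kind,
        target_date = instances$target_date,
        n_prior_cms = instances$n_prior_cms,
        y_true = instances$y
      )
    }
    ctx <- raw_last_values(registry, instances, fit$lag_days)
    list(keys = keys, R = R, ctx = ctx)
  }
  tr <- part(train_ids)
  te <- part(test_ids)
  structure(
    list(train = tr$keys, test = te$keys, R_train = tr$R, R_test = te$R,
         context_train = tr$ctx, context_test = te$ctx, space = space),
    class = "das_embedding_index"
  )
}

#' @export
print.das_embedding_index <- function(x, ...) {
  cat("<das_embedding_index>", nrow(x$R_train), "train /", nrow(x$R_test),
      "test embeddings in", x$space, "space, dim", ncol(x$R_train), "\n")
  invisible(x)
}

l1_distances <- function(R_train, e) {
  colSums(abs(t(R_train) - e))
}

#' Retrieve the nearest training embeddings of a query
#'
#' L1 (Manhattan) distances from the query to every training embedding;
#' the `k` smallest are returned, ties broken by the stable training order
#' (patient id, target index).
#'
#' @param index A `das_embedding_index`.
#' @param e Query: either a numeric vector in the index's embedding space or
#'   a single row number of `index$R_test`.
#' @param k Neighbourhood size.
#' @return List with `neighbours` (row indices into the training set),
#'   `distances` (non-decreasing), and the neighbours' `y` and `score_kind`.
#' @export
knn_query <- function(index, e, k = 50L) {
  if (k < 1L) abort("`k` must be at least 1.")
  if (length(e) == 1L && e == round(e) && e <= nrow(index$R_test)) {
    e <- index$R_test[e, ]
  }
  d <- l1_distances(index$R_train, e)
  k <- min(k, length(d))
  ord <- order(d)[seq_len(k)]
  list(
    neighbours = ord, distances = d[ord],
    y = index$train$y_true[ord], score_kind = index$train$score_kind[ord]
  )
}

# neighbour index matrix for all test embeddings (n_test x k)
knn_neighbour_matrix <- function(index, k = 50L) {
  n <- nrow(index$R_test)
  k <- min(k, nrow(index$R_train))
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    out[i, ] <- order(l1_distances(index$R_train, index$R_test[i, ]))[
      seq_len(k)
    ]
  }
  out
}

knn_predictions <- function(index, nn_mat) {
  n <- nrow(nn_mat)
  pred <- rep(NA_real_, n)
  n_used <- integer(n)
  tr_y <- index$train$y_true
  tr_kind <- index$train$score_kind
  for (i in seq_len(n)) {
    kind <- index$test$score_kind[i]
    nb <- nn_mat[i, ]
    ok <- tr_kind[nb] == kind & !is.na(tr_y[nb])
    n_used[i] <- sum(ok)
    pred[i] <- if (n_used[i] > 0L) {
      mean(tr_y[nb][ok])
    } else {
      mean(tr_y[tr_kind == kind], na.rm = TRUE) # fallback, flagged below
    }
  }
  tibble(
    patient_id = index$test$patient_id,
    target_index = index$test$target_index,
    score_kind = index$test$score_kind,
    n_prior_cms = index$test$n_prior_cms,
    y_true = index$test$y_true, y_pred = pred,
    n_used = n_used, flagged = n_used == 0L
  )
}

#' k-NN regression over the embedding index
#'
#' Predicts each test embedding's future score as the arithmetic mean of its
#' neighbours' targets of the same score kind; neighbours with a different
#' or missing target are excluded from the mean.
#'
#' @param index A `das_embedding_index`.
#' @param k Neighbourhood size.
#' @return List of class `das_knn`: `predictions` tibble (with `model`
#'   column) and `mse` tibble per score kind.
#' @export
knn_regress <- function(index, k = 50L) {
  nn <- knn_neighbour_matrix(index, k)
  preds <- knn_predictions(index, nn) |>
    mutate(model = if (index$space == "latent") "knn_latent" else "knn_raw")
  structure(
    list(predictions = preds, mse = knn_mse(preds), k = k,
         neighbours = nn),
    class = "das_knn"
  )
}

knn_mse <- function(preds) {
  preds |>
    filter(!is.na(.data$y_pred)) |>
    group_by(.data$score_kind) |>
    summarise(mse = mean((.data$y_pred - .data$y_true)^2), n = n(),
              .groups = "drop")
}

#' Random-subset retrieval baseline
#'
#' Replaces the nearest neighbours with a uniformly random subset of training
#' embeddings of size `k` per test embedding; otherwise identical to
#' [knn_regress()].
#'
#' @param index A `das_embedding_index`.
#' @param k Subset size.
#' @param seed Seed for the subsets.
#' @return A `das_knn` object with `model = "random"`.
#' @export
random_subset_baseline <- function(index, k = 50L, seed = 1L) {
  set.seed(seed)
  n_tr <- nrow(index$R_train)
  k <- min(k, n_tr)
  nn <- t(vapply(seq_len(nrow(index$R_test)),
                 function(i) sample.int(n_tr, k), integer(k)))
  preds <- knn_predictions(index, nn) |> mutate(model = "random")
  structure(list(predictions = preds, mse = knn_mse(preds), k = k,
                 neighbours = nn),
            class = "das_knn")
}

#' @export
print.das_knn <- function(x, ...) {
  cat("<das_knn> k =", x$k, "\n")
  print(x$mse)
  invisible(x)
}

# ---- feature importance ------------------------------------------------------

context_feature <- function(ctx, feature) {
  if (!feature %in% names(ctx)) {
    abort(sprintf("Feature '%s' not in the embedding context.", feature))
  }
  ctx[[feature]]
}

#' Average absolute distance of a continuous feature
#'
#' For each test embedding with the feature available, the absolute
#' difference between its feature value and the mean value among its
#' nearest neighbours with the feature available; averaged over those test
#' embeddings. The standardised AAD divides by the feature's standard
#' deviation (computed over training embeddings with the feature available),
#' making the statistic comparable across feature scales.
#'
#' @param index A `das_embedding_index`.
#' @param feature Name of a continuous context feature.
#' @param k Neighbourhood size.
#' @param neighbours Optional precomputed neighbour matrix from
#'   [knn_regress()] (`$neighbours`), to avoid recomputing distances.
#' @return Tibble `feature`, `aad`, `aad_std`, `n` (test embeddings used).
#' @export
aad <- function(index, feature, k = 50L, neighbours = NULL) {
  if (is.null(neighbours)) neighbours <- knn_neighbour_matrix(index, k)
  x_test <- as.numeric(context_feature(index$context_test, feature))
  x_train <- as.numeric(context_feature(index$context_train, feature))
  devs <- rep(NA_real_, length(x_test))
  for (i in seq_along(x_test)) {
    if (is.na(x_test[i])) next
    nv <- x_train[neighbours[i, ]]
    nv <- nv[!is.na(nv)]
    if (length(nv) == 0L) next
    devs[i] <- abs(x_test[i] - mean(nv))
  }
  used <- !is.na(devs)
  if (!any(used)) {
    return(tibble(feature = feature, aad = NA_real_, aad_std = NA_real_,
                  n = 0L))
  }
  a <- mean(devs[used])
  s <- sd(x_train[!is.na(x_train)])
  tibble(feature = feature, aad = a,
         aad_std = if (isTRUE(s > 0)) a / s else NA_real_,
         n = sum(used))
}

#' Prior and adjusted probabilities of a categorical feature
#'
#' The prior probability of a category is its empirical frequency among
#' training embeddings with the feature available. The adjusted probability
#' of category `k` is the frequency of `k` among the pooled neighbours of
#' test embeddings whose own value is `k`. The percentage increase of
#' adjusted over prior measures how strongly the neighbourhood retrieval
#' preserves the category.
#'
#' @inheritParams aad
#' @param feature Name of a categorical context feature.
#' @return Tibble `feature`, `category`, `prior`, `adjusted`,
#'   `increase_pct` (rounded to whole percent; `NA` when the category does
#'   not occur among test embeddings).
#' @export
category_importance <- function(index, feature, k = 50L, neighbours = NULL) {
  if (is.null(neighbours)) neighbours <- knn_neighbour_matrix(index, k)
  x_test <- as.character(context_feature(index$context_test, feature))
  x_train <- as.character(context_feature(index$context_train, feature))
  cats <- sort(unique(x_train[!is.na(x_train)]))
  if (length(cats) == 0L) {
    abort(sprintf("Feature '%s' has no observed categories.", feature))
  }
  prior <- vapply(cats, function(cc) {
    sum(x_train == cc, na.rm = TRUE) / sum(!is.na(x_train))
  }, numeric(1))
  adjusted <- rep(NA_real_, length(cats))
  names(adjusted) <- cats
  for (ci in seq_along(cats)) {
    cc <- cats[ci]
    idx_cc <- which(!is.na(x_test) & x_test == cc)
    if (length(idx_cc) == 0L) next
    num <- 0
    den <- 0
    for (i in idx_cc) {
      nv <- x_train[neighbours[i, ]]
      nv <- nv[!is.na(nv)]
      num <- num + sum(nv == cc)
      den <- den + length(nv)
    }
    if (den > 0) adjusted[ci] <- num / den
  }
  tibble(
    feature = feature, category = cats, prior = unname(prior),
    adjusted = unname(adjusted),
    increase_pct = round(100 * (adjusted - prior) / prior)
  )
}

#' Feature-importance report over all context features
#'
#' Runs [aad()] on every continuous context feature and
#' [category_importance()] on every categorical one, with a shared
#' neighbour matrix.
#'
#' @param index A `das_embedding_index`.
#' @param k Neighbourhood size.
#' @return List with tibbles `continuous` (ordered by standardised AAD) and
#'   `categorical` (ordered by decreasing increase).
#' @export
feature_importance_report <- function(index, k = 50L) {
  nn <- knn_neighbour_matrix(index, k)
  ctx <- index$context_test
  skip <- c("patient_id", "target_index", "score_kind", "target_date")
  cont <- names(ctx)[vapply(ctx, is.numeric, logical(1))]
  cont <- setdiff(cont, skip)
  cat_cols <- setdiff(names(ctx)[vapply(ctx, is.character, logical(1))], skip)
  continuous <- bind_rows(lapply(cont, function(f) {
    aad(index, f, k, neighbours = nn)
  })) |> arrange(.data$aad_std)
  categorical <- bind_rows(lapply(cat_cols, function(f) {
    category_importance(index, f, k, neighbours = nn)
  })) |> arrange(desc(.data$increase_pct))
  list(continuous = continuous, categorical = categorical)
}
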