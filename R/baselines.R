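# Comparison models: naive last-value carry-forward, a feed-forward network
# on last available feature values (one per prediction task), and a single
# concatenated-sequence recurrent model.

#' Naive last-value predictions
#'
#' Predicts every target with the most recent prior value of the same score
#' in the instance's eligible history. When no same-kind score is eligible,
#' the most recent eligible score of either kind is used and the prediction
#' is flagged; when the eligible history holds no score at all the
#' prediction is `NA` (flagged) — the baseline never looks inside the
#' eligibility window, so it sees exactly the information available to the
#' other models.
#'
#' @param registry A `das_registry`.
#' @param instances Instance tibble from [build_instances()]; built from
#'   `registry` when omitted.
#' @param lag_days Eligibility cutoff in days.
#' @return Prediction tibble with `model = "naive"` and a `flagged` column.
#' @export
naive_baseline <- function(registry, instances = NULL, lag_days = 15L) {
  if (is.null(instances)) instances <- build_instances(registry, lag_days)
  instances <- filter(instances, !is.na(.data$y))
  cm <- arrange(registry$clinical_measures, .data$date)
  cm_by <- split(cm, cm$patient_id)
  pred <- numeric(nrow(instances))
  flagged <- logical(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    p <- cm_by[[instances$patient_id[i]]]
    kind <- instances$score_kind[i]
    d <- as.numeric(p$date)
    tv <- as.numeric(instances$target_date[i])
    same <- p[[kind]]
    other <- p[[setdiff(SCORE_KINDS, kind)]]
    pick <- function(vals, cut) {
      v <- vals[d <= cut & !is.na(vals)]
      if (length(v)) v[length(v)] else NA_real_
    }
    cutoff <- tv - lag_days
    val <- pick(same, cutoff)
    if (is.na(val)) {
      flagged[i] <- TRUE
      val <- pick(other, cutoff)
    }
    pred[i] <- val
  }
  tibble(
    patient_id = instances$patient_id,
    target_index = instances$target_index,
    score_kind = instances$score_kind,
    target_date = instances$target_date,
    n_prior_cms = instances$n_prior_cms,
    y_true = instances$y, y_pred = pred,
    model = "naive", flagged = flagged
  )
}

# mini-batch AdamW regression on a fixed feature matrix, early-stopped on a
# held-out validation subset (grouped by patient when groups are given)
fit_mlp_regressor <- function(X, y, hidden, epochs, lr, batch = 64L,
                              weight_decay = 1e-4, seed = 1L,
                              groups = NULL, val_fraction = 0.15,
                              patience = 15L) {
  set.seed(seed)
  n <- nrow(X)
  groups <- groups %||% as.character(seq_len(n))
  val_groups <- sample(unique(groups),
                       max(1L, round(length(unique(groups)) * val_fraction)))
  val <- groups %in% val_groups
  fit_idx <- which(!val)
  p <- init_mlp(c(ncol(X), hidden, 1L))
  opt <- adamw_init(p)
  best <- list(loss = Inf, p = p)
  wait <- 0L
  for (e in seq_len(epochs)) {
    ord <- sample(fit_idx)
    for (ch in split(ord, ceiling(seq_along(ord) / batch))) {
      fw <- mlp_forward(p, X[ch, , drop = FALSE])
      d <- 2 * (fw$out - y[ch]) / length(ch)
      g <- mlp_backward(p, fw$cache, d)$grads
      upd <- adamw_step(p, g, opt, lr, weight_decay)
      p <- upd$params
      opt <- upd$state
    }
    vl <- mean((mlp_forward(p, X[val, , drop = FALSE])$out - y[val])^2)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, p = p)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best$p
}

#' Fit the feed-forward (last-value) baseline
#'
#' One MLP regressor per prediction task, taking as input the last available
#' value of every feature in the eligible history (see
#' [build_last_value_features()]). By construction the model is insensitive
#' to any event that is not the most recent carrier of a feature.
#'
#' @param registry A filtered `das_registry`.
#' @param split Split tibble from [stratified_split()].
#' @param hidden Hidden-layer widths.
#' @param epochs,lr Optimiser settings.
#' @param lag_days Eligibility cutoff.
#' @param seed Seed for initialisation and batching.
#' @return An object of class `das_mlp_baseline` with a `predict()` method.
#' @export
fit_mlp_baseline <- function(registry, split, hidden = c(32L, 16L),
                             epochs = 150L, lr = 1e-3, lag_days = 15L,
                             seed = 1L) {
  train_ids <- split$patient_id[split$split == "train"]
  instances <- filter(build_instances(registry, lag_days), !is.na(.data$y))
  std <- fit_standardiser(registry, train_ids)
  inst_train <- filter(instances, .data$patient_id %in% train_ids)
  t_ok <- inst_train$t_days[!is.na(inst_train$t_days)]
  t_stats <- list(mean = if (length(t_ok)) mean(t_ok) else 0,
                  sd = if (length(t_ok) > 1L && sd(t_ok) > 0) sd(t_ok) else 1)
  lv <- build_last_value_features(registry, inst_train, std, t_stats,
                                  lag_days)
  models <- list()
  y_stats <- list()
  for (s in SCORE_KINDS) {
    sel <- inst_train$score_kind == s
    if (!any(sel)) next
    y <- inst_train$y[sel]
    y_stats[[s]] <- list(mean = mean(y), sd = if (sd(y) > 0) sd(y) else 1)
    models[[s]] <- fit_mlp_regressor(
      lv$X[sel, , drop = FALSE],
      (y - y_stats[[s]]$mean) / y_stats[[s]]$sd,
      hidden, epochs, lr, seed = seed,
      groups = inst_train$patient_id[sel]
    )
  }
  structure(
    list(models = models, std = std, t_stats = t_stats, y_stats = y_stats,
         lag_days = lag_days, split = split),
    class = "das_mlp_baseline"
  )
}

#' @export
predict.das_mlp_baseline <- function(object, registry, patients = NULL, ...) {
  instances <- filter(build_instances(registry, object$lag_days),
                      !is.na(.data$y))
  if (!is.null(patients)) {
    instances <- filter(instances, .data$patient_id %in% patients)
  }
  lv <- build_last_value_features(registry, instances, object$std,
                                  object$t_stats, object$lag_days)
  pred <- rep(NA_real_, nrow(instances))
  for (s in names(object$models)) {
    sel <- instances$score_kind == s
    if (!any(sel)) next
    z <- mlp_forward(object$models[[s]], lv$X[sel, , drop = FALSE])$out[, 1L]
    pred[sel] <- z * object$y_stats[[s]]$sd + object$y_stats[[s]]$mean
  }
  tibble(
    patient_id = instances$patient_id,
    target_index = instances$target_index,
    score_kind = instances$score_kind,
    target_date = instances$target_date,
    n_prior_cms = instances$n_prior_cms,
    y_true = instances$y, y_pred = pred, model = "mlp"
  )
}

#' Fit the concatenated-sequence recurrent baseline
#'
#' A single recurrent model over the union of all time-related events,
#' date-sorted, with per-kind feature blocks (zeros outside the event's own
#' block) and kind-indicator features — in contrast to the main model's
#' per-source temporal blocks. Optimisation matches [dasnet()].
#'
#' @inheritParams dasnet
#' @return An object of class `dasnet` (with `merged = TRUE`); all `dasnet`
#'   methods apply.
#' @export
fit_lstm_baseline <- function(registry, split, config = dasnet_config(),
                              control = dasnet_control(), lag_days = 15L) {
  prep <- prepare_training(registry, split, lag_days, merged = TRUE,
                           control$val_fraction, control$seed)
  core <- dasnet_fit_core(prep$md, prep$fit_rows, prep$val_rows, config,
                          control)
  structure(
    list(params = core$params, config = config, std = prep$std,
         t_stats = prep$t_stats, y_stats = prep$y_stats, log = core$log,
         best_epoch = core$best_epoch, best_val_loss = core$best_val_loss,
         split = split, lag_days = lag_days, merged = TRUE,
         control = control),
    class = "dasnet"
  )
}
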