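# Shared regression and classification evaluation.

ACTIVITY_THRESHOLDS <- c(das28 = 2.6, asdas = 2.0)

#' Per-score mean squared error with bootstrap uncertainty
#'
#' @param predictions Prediction tibble with `score_kind`, `y_true`,
#'   `y_pred` (and optionally `model`).
#' @param n_boot Bootstrap resamples over instances for the MSE standard
#'   deviation (0 disables).
#' @param seed Bootstrap seed.
#' @return Tibble with one row per (model,) score kind: `mse`, `mse_sd`, `n`.
#' @export
mse_report <- function(predictions, n_boot = 200L, seed = 1L) {
  predictions <- filter(predictions, !is.na(.data$y_pred))
  if (!"model" %in% names(predictions)) predictions$model <- "model"
  if (nrow(predictions) == 0L) {
    warn("No predictions to evaluate.")
    return(tibble(model = character(), score_kind = character(),
                  mse = numeric(), mse_sd = numeric(), n = integer()))
  }
  set.seed(seed)
  predictions |>
    group_by(.data$model, .data$score_kind) |>
    summarise(
      mse = mean((.data$y_pred - .data$y_true)^2),
      mse_sd = if (n_boot > 0L) {
        e2 <- (.data$y_pred - .data$y_true)^2
        sd(vapply(seq_len(n_boot), function(b) {
          mean(e2[sample.int(length(e2), replace = TRUE)])
        }, numeric(1)))
      } else {
        NA_real_
      },
      n = n(), .groups = "drop"
    )
}

#' MSE as a function of history length
#'
#' @param predictions Prediction tibble carrying `n_prior_cms`.
#' @param max_bin History lengths above this are pooled.
#' @return Tibble `score_kind`, `n_prior_cms` (character, last bin pooled),
#'   `mse`, `n`.
#' @export
mse_vs_history <- function(predictions, max_bin = 8L) {
  predictions |>
    filter(!is.na(.data$y_pred)) |>
    mutate(bin = pmin(.data$n_prior_cms, max_bin)) |>
    group_by(.data$score_kind, .data$bin) |>
    summarise(mse = mean((.data$y_pred - .data$y_true)^2), n = n(),
              .groups = "drop") |>
    rename(n_prior_cms = "bin")
}

#' Classification metrics from confusion counts
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return Tibble `sensitivity`, `specificity`, `accuracy` (with the counts).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / (tp + tn + fp + fn)
  )
}

active_label <- function(y, score_kind) {
  y > ACTIVITY_THRESHOLDS[score_kind] # strict: a score AT the threshold is
  # not active
}

#' Active-disease classification performance
#'
#' Active disease is defined on the true values as DAS28 strictly above 2.6
#' or ASDAS strictly above 2.0. In `"threshold"` mode the predicted scores
#' are thresholded the same way. In `"logistic"` mode a logistic regression
#' is trained on the training-set latent embeddings (per score kind) and
#' evaluated on the test embeddings.
#'
#' @param x A prediction tibble (`threshold` mode) or a
#'   `das_embedding_index` (`logistic` mode).
#' @param mode `"threshold"` or `"logistic"`.
#' @return Tibble per score kind with confusion counts, sensitivity,
#'   specificity and accuracy (metrics are `NA` when a class is absent from
#'   the test truth).
#' @export
classify_active <- function(x, mode = c("threshold", "logistic")) {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    df <- filter(x, !is.na(.data$y_pred))
    parts <- lapply(split(df, df$score_kind), function(sub) {
      kind <- sub$score_kind[1L]
      truth <- active_label(sub$y_true, kind)
      pred <- active_label(sub$y_pred, kind)
      bind_cols(tibble(score_kind = kind), confusion_for(truth, pred))
    })
    return(bind_rows(parts))
  }
  index <- x
  parts <- list()
  for (kind in unique(index$test$score_kind)) {
    tr <- index$train$score_kind == kind
    te <- index$test$score_kind == kind
    y_tr <- active_label(index$train$y_true[tr], kind)
    y_te <- active_label(index$test$y_true[te], kind)
    dtr <- as.data.frame(index$R_train[tr, , drop = FALSE])
    dte <- as.data.frame(index$R_test[te, , drop = FALSE])
    names(dte) <- names(dtr)
    if (length(unique(y_tr)) < 2L) {
      warn(sprintf("Only one class present in training truth for %s.", kind))
      next
    }
    m <- suppressWarnings(
      glm(y ~ ., data = cbind(y = y_tr, dtr), family = binomial())
    )
    p <- predict(m, newdata = dte, type = "response") > 0.5
    parts[[kind]] <- bind_cols(tibble(score_kind = kind),
                               confusion_for(y_te, p))
  }
  bind_rows(parts)
}

confusion_for <- function(truth, pred) {
  confusion_metrics(
    tp = sum(truth & pred), tn = sum(!truth & !pred),
    fp = sum(!truth & pred), fn = sum(truth & !pred)
  )
}

#' Consolidated model comparison
#'
#' Stacks prediction tibbles from several models and ranks them per score
#' kind by MSE (ties broken by model name). Input numbers are reproduced
#' exactly; nothing is re-fitted.
#'
#' @param predictions Named list of prediction tibbles, or one tibble with a
#'   `model` column.
#' @param n_boot Passed to [mse_report()].
#' @return Tibble ranked within score kind.
#' @export
compare_models <- function(predictions, n_boot = 0L) {
  if (is.data.frame(predictions)) {
    all_preds <- predictions
  } else {
    all_preds <- bind_rows(imap(predictions, function(p, nm) {
      p$model <- nm
      p
    }))
  }
  mse_report(all_preds, n_boot = n_boot) |>
    group_by(.data$score_kind) |>
    arrange(.data$mse, .data$model, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}
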