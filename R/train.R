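# Multi-task optimisation: per-step loss over a pair of score-specific
# patient batches, AdamW with gradient clipping, early stopping on a
# validation split, and five-fold cross-validation with random search.

#' Multi-task batch loss from prediction/target pairs
#'
#' Computes the training objective
#' \deqn{L = \sum_{B \in \{B_{DAS28}, B_{ASDAS}\}} \frac{1}{N_B}
#'   \sum_{p \in B} \sum_{v=1}^{n_p} (\hat y_{pv} - y_{pv})^2,}
#' i.e. the sum over the two score batches of the mean squared error over all
#' targets in the batch. An empty batch contributes 0 (with a warning).
#'
#' @param pred_tbl Tibble with columns `batch` (score kind of the batch the
#'   target belongs to), `pred` and `y`.
#' @return The scalar loss.
#' @export
loss_eq1 <- function(pred_tbl) {
  total <- 0
  for (s in SCORE_KINDS) {
    sub <- pred_tbl[pred_tbl$batch == s, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warn(sprintf("Batch for %s is empty; it contributes 0 to the loss.", s))
      next
    }
    total <- total + sum((sub$pred - sub$y)^2) / nrow(sub)
  }
  total
}

# forward both batches of a batch pair; returns per-batch forwards and the
# tibble loss_eq1() consumes
forward_batch_pair <- function(params, md, batch_pair, config,
                               train = FALSE) {
  fwds <- list()
  parts <- list()
  for (s in SCORE_KINDS) {
    rows <- batch_pair[[s]]
    if (length(rows) == 0L) next
    b <- make_batch(md, rows)
    fwds[[s]] <- dasnet_batch_forward(params, b, config, train = train)
    parts[[s]] <- tibble(batch = s, pred = fwds[[s]]$pred, y = b$y)
  }
  list(fwds = fwds, pred_tbl = bind_rows(parts))
}

#' Evaluate the multi-task loss for a batch pair
#'
#' Runs the network forward on the two score-specific batches and evaluates
#' the training objective (see [loss_eq1()]).
#'
#' @param params A parameter set.
#' @param md Model data (internal structure built by the fitting functions).
#' @param batch_pair List with elements `das28` and `asdas`, each a vector of
#'   instance row indices into `md$instances`.
#' @param config The `dasnet_config` the parameters were created with.
#' @return The scalar loss.
#' @export
compute_loss <- function(params, md, batch_pair, config) {
  fp <- forward_batch_pair(params, md, batch_pair, config)
  loss_eq1(fp$pred_tbl)
}

#' Sample the dual-batch schedule for one epoch
#'
#' At every optimiser step one batch of patients with DAS28 targets and one
#' with ASDAS targets is drawn; all available targets of a sampled patient
#' enter the step. Patients are sampled without replacement within the epoch,
#' and the two batch sizes are proportional to the total number of available
#' targets per score (rounded, minimum 1).
#'
#' @param instances Instance tibble (rows index the training set).
#' @param base_batch Total number of patients per step before the
#'   proportional split between the two scores.
#' @return List of steps; each step is a list with elements `das28` and
#'   `asdas` holding instance row indices.
#' @export
sample_dual_batches <- function(instances, base_batch = 32L) {
  sizes <- batch_sizes(
    c(das28 = sum(instances$score_kind == "das28"),
      asdas = sum(instances$score_kind == "asdas")),
    base_batch
  )
  pat_rows <- list()
  pats <- list()
  for (s in SCORE_KINDS) {
    rows <- which(instances$score_kind == s)
    pr <- split(rows, instances$patient_id[rows])
    pats[[s]] <- if (length(pr) > 0L) sample(names(pr)) else character(0)
    pat_rows[[s]] <- pr
  }
  per_score_steps <- vapply(SCORE_KINDS, function(s) {
    if (sizes[s] == 0L) 0 else ceiling(length(pats[[s]]) / sizes[s])
  }, numeric(1))
  n_steps <- max(1, per_score_steps)
  steps <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    step <- list()
    for (s in SCORE_KINDS) {
      take <- pats[[s]][seq.int(
        from = (i - 1L) * sizes[s] + 1L,
        length.out = sizes[s]
      )]
      take <- take[!is.na(take)]
      step[[s]] <- unlist(pat_rows[[s]][take], use.names = FALSE) %||%
        integer(0)
    }
    steps[[i]] <- step
  }
  steps
}

# per-score batch sizes proportional to total target counts, min 1
batch_sizes <- function(n_targets, base_batch) {
  total <- sum(n_targets)
  if (total == 0L) abort("No targets available.")
  sz <- pmax(round(base_batch * n_targets / total), 1L)
  sz[n_targets == 0L] <- 0L
  sz
}

#' Training control parameters
#'
#' @param lr AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param base_batch Patients per optimiser step (split between the scores
#'   proportionally to target counts).
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs on the validation loss.
#' @param clip_norm Global gradient-norm clip.
#' @param val_fraction Fraction of training patients held out (per score
#'   kind) for early stopping.
#' @param seed Integer seed for initialisation, batching and dropout.
#' @param verbose Print per-epoch losses.
#' @return A list of class `dasnet_control`.
#' @export
dasnet_control <- function(lr = 3e-3, weight_decay = 1e-4, base_batch = 32L,
                           epochs = 100L, patience = 15L, clip_norm = 5,
                           val_fraction = 0.15, seed = 1L, verbose = FALSE) {
  structure(
    list(lr = lr, weight_decay = weight_decay,
         base_batch = as.integer(base_batch), epochs = as.integer(epochs),
         patience = as.integer(patience), clip_norm = clip_norm,
         val_fraction = val_fraction, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "dasnet_control"
  )
}

# choose a patient-level validation subset of the training split, stratified
# by the patient's score kind(s)
choose_val_patients <- function(instances, val_fraction) {
  if (val_fraction <= 0) return(character(0))
  by_kind <- instances |>
    distinct(.data$patient_id, .data$score_kind)
  picks <- lapply(split(by_kind$patient_id, by_kind$score_kind), function(p) {
    p <- unique(p)
    n_val <- max(1L, round(length(p) * val_fraction))
    sample(p, min(n_val, length(p)))
  })
  unique(unlist(picks, use.names = FALSE))
}

# core optimisation loop shared by dasnet() and the recurrent baseline:
# md holds all patients; fit/val instance rows index md$instances.
dasnet_fit_core <- function(md, fit_rows, val_rows, config, control) {
  set.seed(control$seed)
  params <- init_dasnet_params(config, md$input_dims)
  opt <- adamw_init(params)
  inst_fit <- md$instances[fit_rows, , drop = FALSE]
  val_pair <- list(
    das28 = val_rows[md$instances$score_kind[val_rows] == "das28"],
    asdas = val_rows[md$instances$score_kind[val_rows] == "asdas"]
  )
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- list()
  wait <- 0L
  for (epoch in seq_len(control$epochs)) {
    steps <- sample_dual_batches(inst_fit, control$base_batch)
    tr_loss <- 0
    for (st in steps) {
      pair <- list(das28 = fit_rows[st$das28], asdas = fit_rows[st$asdas])
      fp <- forward_batch_pair(params, md, pair, config, train = TRUE)
      if (nrow(fp$pred_tbl) == 0L) next
      loss <- suppressWarnings(loss_eq1(fp$pred_tbl))
      if (!is.finite(loss)) {
        abort(sprintf("Training diverged at epoch %d (non-finite loss).",
                      epoch))
      }
      tr_loss <- tr_loss + loss
      grads <- NULL
      for (s in SCORE_KINDS) {
        fwd <- fp$fwds[[s]]
        if (is.null(fwd)) next
        n_b <- length(fwd$pred)
        d_pred <- 2 * (fwd$pred - fwd$cache$batch$y) / n_b
        g <- dasnet_batch_backward(params, fwd, d_pred, config)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      grads <- tree_clip_global_norm(grads, control$clip_norm)
      upd <- adamw_step(params, grads, opt, control$lr, control$weight_decay)
      params <- upd$params
      opt <- upd$state
    }
    val_loss <- if (length(val_rows) > 0L) {
      suppressWarnings(compute_loss(params, md, val_pair, config))
    } else {
      tr_loss / max(1L, length(steps))
    }
    log[[epoch]] <- tibble(
      epoch = epoch, train_loss = tr_loss / max(1L, length(steps)),
      val_loss = val_loss
    )
    if (control$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      log[[epoch]]$train_loss, val_loss))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  list(params = best$params, log = bind_rows(log), best_epoch = best$epoch,
       best_val_loss = best$loss)
}

# shared preparation: filter split, fit standardiser on training patients,
# standardise targets and time-to-prediction on the training instances
prepare_training <- function(registry, split, lag_days, merged,
                             val_fraction, seed) {
  train_ids <- split$patient_id[split$split == "train"]
  instances <- build_instances(registry, lag_days)
  instances <- filter(instances, !is.na(.data$y))
  std <- fit_standardiser(registry, train_ids)
  inst_train <- filter(instances, .data$patient_id %in% train_ids)
  t_ok <- inst_train$t_days[!is.na(inst_train$t_days)]
  t_stats <- list(
    mean = if (length(t_ok)) mean(t_ok) else 0,
    sd = if (length(t_ok) > 1L && sd(t_ok) > 0) sd(t_ok) else 1
  )
  y_stats <- lapply(split(inst_train$y, inst_train$score_kind),
                    function(y) list(mean = mean(y),
                                     sd = if (sd(y) > 0) sd(y) else 1))
  md <- build_model_data(registry, std, instances, t_stats, merged = merged)
  # train the network on standardised targets; predictions are mapped back
  md$instances$y_raw <- md$instances$y
  for (s in names(y_stats)) {
    sel <- md$instances$score_kind == s
    md$instances$y[sel] <-
      (md$instances$y[sel] - y_stats[[s]]$mean) / y_stats[[s]]$sd
  }
  set.seed(seed)
  inst_tr_rows <- which(md$instances$patient_id %in% train_ids)
  val_ids <- choose_val_patients(md$instances[inst_tr_rows, ], val_fraction)
  fit_rows <- inst_tr_rows[!(md$instances$patient_id[inst_tr_rows] %in% val_ids)]
  val_rows <- inst_tr_rows[md$instances$patient_id[inst_tr_rows] %in% val_ids]
  list(md = md, std = std, t_stats = t_stats, y_stats = y_stats,
       fit_rows = fit_rows, val_rows = val_rows, train_ids = train_ids)
}

#' Fit the multi-task disease activity network
#'
#' Trains the attention network on the training patients of `split`:
#' standardises features and targets on the training split, holds out a
#' patient-level validation subset for early stopping, optimises the
#' multi-task objective with AdamW over dual score-specific patient batches,
#' and returns the best-validation checkpoint.
#'
#' @param registry A filtered `das_registry`.
#' @param split Split tibble from [stratified_split()].
#' @param config A [dasnet_config()].
#' @param control A [dasnet_control()].
#' @param lag_days Eligibility cutoff in days between input events and the
#'   target.
#' @return An object of class `dasnet` with elements `params`, `config`,
#'   `std` (standardiser), `t_stats`, `y_stats`, `log` (per-epoch losses),
#'   `best_epoch`, `split`, `lag_days`.
#' @examples
#' \donttest{
#' reg <- simulate_registry(sim_config(n_patients = 40, seed = 2)) |>
#'   filter_patients() |>
#'   select_medications()
#' sp <- stratified_split(reg, seed = 2)
#' fit <- dasnet(reg, sp, control = dasnet_control(epochs = 3))
#' predict(fit, reg)
#' }
#' @export
dasnet <- function(registry, split, config = dasnet_config(),
                   control = dasnet_control(), lag_days = 15L) {
  prep <- prepare_training(registry, split, lag_days, merged = FALSE,
                           control$val_fraction, control$seed)
  core <- dasnet_fit_core(prep$md, prep$fit_rows, prep$val_rows, config,
                          control)
  structure(
    list(params = core$params, config = config, std = prep$std,
         t_stats = prep$t_stats, y_stats = prep$y_stats, log = core$log,
         best_epoch = core$best_epoch, best_val_loss = core$best_val_loss,
         split = split, lag_days = lag_days, merged = FALSE,
         control = control),
    class = "dasnet"
  )
}

#' @export
print.dasnet <- function(x, ...) {
  cat("<dasnet> latent size", x$config$r, "|",
      tree_n_params(x$params), "parameters | best epoch",
      x$best_epoch, sprintf("(val loss %.4f)\n", x$best_val_loss))
  invisible(x)
}

# run the fitted network over instances of a registry; returns predictions,
# representations and attention records
dasnet_infer <- function(object, registry, patients = NULL,
                         chunk_size = 512L) {
  instances <- build_instances(registry, object$lag_days)
  instances <- filter(instances, !is.na(.data$y))
  if (!is.null(patients)) {
    instances <- filter(instances, .data$patient_id %in% patients)
  }
  md <- build_model_data(registry, object$std, instances, object$t_stats,
                         merged = object$merged)
  n <- nrow(md$instances)
  if (n == 0L) abort("No instances to predict.")
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  preds <- numeric(n)
  R <- NULL
  glob <- NULL
  locals <- list()
  for (ch in chunks) {
    b <- make_batch(md, ch)
    fwd <- dasnet_batch_forward(object$params, b, object$config)
    preds[ch] <- fwd$pred
    R <- rbind(R, fwd$R)
    glob <- rbind(glob, fwd$global)
    locals[[length(locals) + 1L]] <- fwd$local
  }
  inst <- md$instances
  if (!"y_raw" %in% names(inst)) inst$y_raw <- inst$y
  for (s in names(object$y_stats)) {
    sel <- inst$score_kind == s
    preds[sel] <- preds[sel] * object$y_stats[[s]]$sd +
      object$y_stats[[s]]$mean
  }
  list(instances = inst, pred = preds, R = R, global = glob,
       locals = locals, chunks = chunks, kinds = md$kinds)
}

#' Predict disease activity scores for registry instances
#'
#' @param object A fitted `dasnet`.
#' @param registry The registry to build prediction instances from.
#' @param patients Optional subset of patient ids (e.g. the test split).
#' @param ... Unused.
#' @return Tibble `patient_id`, `target_index`, `score_kind`, `target_date`,
#'   `n_prior_cms`, `y_true`, `y_pred`.
#' @export
predict.dasnet <- function(object, registry, patients = NULL, ...) {
  inf <- dasnet_infer(object, registry, patients)
  tibble(
    patient_id = inf$instances$patient_id,
    target_index = inf$instances$target_index,
    score_kind = inf$instances$score_kind,
    target_date = inf$instances$target_date,
    n_prior_cms = inf$instances$n_prior_cms,
    y_true = inf$instances$y_raw,
    y_pred = inf$pred
  )
}

#' Latent representations of registry instances
#'
#' @inheritParams predict.dasnet
#' @param object A fitted `dasnet`.
#' @return Tibble of instance keys plus the representation columns
#'   `R1 ... Rr` (the last column is the standardised time-to-prediction).
#' @export
dasnet_embed <- function(object, registry, patients = NULL) {
  inf <- dasnet_infer(object, registry, patients)
  R <- inf$R
  colnames(R) <- paste0("R", seq_len(ncol(R)))
  bind_cols(
    tibble(
      patient_id = inf$instances$patient_id,
      target_index = inf$instances$target_index,
      score_kind = inf$instances$score_kind,
      target_date = inf$instances$target_date,
      n_prior_cms = inf$instances$n_prior_cms,
      y_true = inf$instances$y_raw
    ),
    as_tibble(R)
  )
}

#' Attention records of registry instances
#'
#' @inheritParams predict.dasnet
#' @param object A fitted `dasnet`.
#' @return A list of two tibbles. `global`: one row per instance and source
#'   (`cm`, `med`, `prom`, `dem`) with the global attention weight.
#'   `local`: one row per instance, event kind and event position with the
#'   local attention weight and the position counted from the end of the
#'   eligible history (`reverse_position` 1 = most recent event).
#' @export
dasnet_attention <- function(object, registry, patients = NULL) {
  inf <- dasnet_infer(object, registry, patients)
  keys <- tibble(
    patient_id = inf$instances$patient_id,
    target_index = inf$instances$target_index,
    score_kind = inf$instances$score_kind,
    n_prior_cms = inf$instances$n_prior_cms,
    y_true = inf$instances$y_raw
  )
  glob <- bind_cols(keys, as_tibble(inf$global)) |>
    tidyr::pivot_longer(dplyr::all_of(colnames(inf$global)),
                        names_to = "source", values_to = "weight")
  loc_parts <- list()
  for (ci in seq_along(inf$chunks)) {
    rows <- inf$chunks[[ci]]
    for (kd in inf$kinds) {
      aw <- inf$locals[[ci]][[kd]]
      if (is.null(aw)) next
      for (j in seq_len(ncol(aw))) {
        ok <- !is.na(aw[, j])
        if (!any(ok)) next
        n_ev <- rowSums(!is.na(aw))
        loc_parts[[length(loc_parts) + 1L]] <- bind_cols(
          keys[rows[ok], ],
          tibble(kind = kd, position = j,
                 reverse_position = n_ev[ok] - j + 1L,
                 weight = aw[ok, j])
        )
      }
    }
  }
  list(global = glob, local = bind_rows(loc_parts))
}

# ---- cross-validation with random hyper-parameter search --------------------

#' Random-search space for cross-validation
#'
#' @param q Candidate embedding sizes.
#' @param encoder_hidden Candidate encoder hidden widths (one value is used
#'   for both encoder layers).
#' @param head_hidden Candidate head hidden widths.
#' @param lr_range Log-uniform learning-rate range.
#' @param dropout Candidate dropout rates.
#' @return A list of class `dasnet_search_space`.
#' @export
dasnet_search_space <- function(q = c(8L, 12L, 16L),
                                encoder_hidden = c(16L, 32L, 64L),
                                head_hidden = c(16L, 32L),
                                lr_range = c(1e-4, 1e-2),
                                dropout = c(0, 0.1, 0.2)) {
  structure(list(q = q, encoder_hidden = encoder_hidden,
                 head_hidden = head_hidden, lr_range = lr_range,
                 dropout = dropout),
            class = "dasnet_search_space")
}

draw_config <- function(space) {
  eh <- sample(space$encoder_hidden, 1L)
  list(
    config = dasnet_config(
      q = sample(space$q, 1L),
      encoder_hidden = c(eh, eh),
      head_hidden = rep(sample(space$head_hidden, 1L), 2L),
      dropout = sample(space$dropout, 1L)
    ),
    lr = exp(runif(1L, log(space$lr_range[1L]), log(space$lr_range[2L])))
  )
}

#' Five-fold cross-validation with random hyper-parameter search
#'
#' For each of `n_draws` randomly sampled configurations, trains on four of
#' the folds defined by [stratified_split()] and evaluates the multi-task
#' loss on the held-out fold; the configuration with the lowest mean
#' validation loss across folds is selected.
#'
#' @param registry A filtered `das_registry`.
#' @param split Split tibble from [stratified_split()] (fold labels are used;
#'   test patients never participate).
#' @param space A [dasnet_search_space()].
#' @param n_draws Number of sampled configurations.
#' @param control Base [dasnet_control()]; the drawn learning rate overrides
#'   `control$lr`.
#' @param lag_days Eligibility cutoff.
#' @param seed Seed for the search.
#' @return An object of class `dasnet_cv`: tibble `results` (one row per
#'   draw and fold), `summary` (mean/sd per draw), and `best` (the selected
#'   configuration).
#' @export
cross_validate <- function(registry, split, space = dasnet_search_space(),
                           n_draws = 5L, control = dasnet_control(),
                           lag_days = 15L, seed = 1L) {
  if (n_draws < 1L) abort("`n_draws` must be at least 1.")
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) draw_config(space))
  folds <- sort(unique(split$fold[!is.na(split$fold)]))
  rows <- list()
  for (d in seq_along(draws)) {
    ctl <- control
    ctl$lr <- draws[[d]]$lr
    ctl$val_fraction <- 0 # the held-out fold is the validation set
    for (f in folds) {
      tr_ids <- split$patient_id[split$split == "train" &
                                   !is.na(split$fold) & split$fold != f]
      va_ids <- split$patient_id[split$split == "train" &
                                   !is.na(split$fold) & split$fold == f]
      sub_split <- mutate(split, split = if_else(
        .data$patient_id %in% va_ids, "test", .data$split
      ))
      prep <- prepare_training(registry, sub_split, lag_days, FALSE,
                               val_fraction = 0, seed = ctl$seed)
      va_rows <- which(prep$md$instances$patient_id %in% va_ids)
      core <- dasnet_fit_core(prep$md, prep$fit_rows, va_rows,
                              draws[[d]]$config, ctl)
      rows[[length(rows) + 1L]] <- tibble(
        draw = d, fold = f, val_loss = core$best_val_loss,
        q = draws[[d]]$config$q,
        encoder_hidden = draws[[d]]$config$encoder_hidden[1L],
        head_hidden = draws[[d]]$config$head_hidden[1L],
        dropout = draws[[d]]$config$dropout, lr = draws[[d]]$lr
      )
    }
  }
  results <- bind_rows(rows)
  summary <- results |>
    group_by(.data$draw) |>
    summarise(mean_val_loss = mean(.data$val_loss),
              sd_val_loss = sd(.data$val_loss), .groups = "drop")
  best_draw <- summary$draw[which.min(summary$mean_val_loss)]
  structure(
    list(results = results, summary = summary,
         best = c(draws[[best_draw]], list(draw = best_draw))),
    class = "dasnet_cv"
  )
}
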