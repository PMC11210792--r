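# Assembly of model-ready data: per-patient encoded event matrices with
# dates, instance metadata, batch construction, and last-value feature
# vectors for the feed-forward baseline and raw-space k-NN.

TIME_KINDS <- c("cm", "med", "prom")
KIND_TABLE <- c(cm = "clinical_measures", med = "medications", prom = "prom")

split_rows <- function(X, ids) {
  idx <- split(seq_along(ids), ids)
  lapply(idx, function(i) X[i, , drop = FALSE])
}

# Build the structure consumed by the network: for every patient the encoded
# event matrices (time-ordered) plus their dates, and the instance table with
# standardised time-to-prediction. merged = TRUE concatenates the three event
# streams into a single date-sorted sequence with per-kind feature blocks and
# kind indicators (the concatenated-sequence recurrent baseline's view).
build_model_data <- function(registry, standardiser, instances, t_stats,
                             merged = FALSE) {
  enc <- apply_standardiser(standardiser, registry)
  pids <- unique(registry$demographics$patient_id)

  dem_rows <- enc$demographics
  dem_map <- split_rows(dem_rows$X, dem_rows$patient_id)

  per_kind <- lapply(TIME_KINDS, function(kd) {
    e <- enc[[KIND_TABLE[kd]]]
    list(
      X = split_rows(e$X, e$patient_id),
      dates = split(as.numeric(e$date), e$patient_id)
    )
  })
  names(per_kind) <- TIME_KINDS

  patients <- lapply(pids, function(pid) {
    p <- list(dem = dem_map[[pid]][1L, ])
    for (kd in TIME_KINDS) {
      X <- per_kind[[kd]]$X[[pid]]
      d <- per_kind[[kd]]$dates[[pid]]
      if (is.null(X)) {
        X <- matrix(0, 0, ncol(enc[[KIND_TABLE[kd]]]$X))
        d <- numeric(0)
      }
      p[[kd]] <- X
      p[[paste0(kd, "_dates")]] <- d
    }
    p
  })
  names(patients) <- pids

  kinds <- TIME_KINDS
  if (merged) {
    dims <- vapply(TIME_KINDS, function(kd) ncol(enc[[KIND_TABLE[kd]]]$X),
                   integer(1))
    offs <- cumsum(c(0, dims))
    p_all <- sum(dims) + length(TIME_KINDS)
    for (pid in pids) {
      p <- patients[[pid]]
      n_ev <- vapply(TIME_KINDS, function(kd) nrow(p[[kd]]), integer(1))
      total <- sum(n_ev)
      X <- matrix(0, total, p_all)
      dts <- numeric(total)
      kind_ord <- integer(total)
      at <- 0L
      for (ki in seq_along(TIME_KINDS)) {
        kd <- TIME_KINDS[ki]
        if (n_ev[ki] == 0L) next
        rows <- at + seq_len(n_ev[ki])
        X[rows, offs[ki] + seq_len(dims[ki])] <- p[[kd]]
        X[rows, sum(dims) + ki] <- 1
        dts[rows] <- p[[paste0(kd, "_dates")]]
        kind_ord[rows] <- ki
        at <- at + n_ev[ki]
      }
      ord <- order(dts, kind_ord) # stable: date, then kind, then file order
      patients[[pid]] <- list(
        dem = p$dem, seq = X[ord, , drop = FALSE], seq_dates = dts[ord]
      )
    }
    kinds <- "seq"
  }

  inst <- instances
  if (merged) {
    inst$n_seq <- inst$n_cm + inst$n_med + inst$n_prom
  }
  inst$t_std <- (inst$t_days - t_stats$mean) / t_stats$sd
  inst$t_std[is.na(inst$t_std)] <- 0

  input_dims <- c(
    vapply(kinds, function(kd) ncol(patients[[pids[1L]]][[kd]]), integer(1)),
    dem = ncol(dem_map[[pids[1L]]])
  )
  names(input_dims) <- c(kinds, "dem")

  list(patients = patients, instances = inst, kinds = kinds,
       input_dims = input_dims)
}

# Assemble a forward-pass batch from instance rows of md$instances.
# For each event kind: the stacked encoded events of all instances (each
# instance contributes the eligible prefix of its patient's matrix), an
# N x T index matrix into the stack (0 = padding) and the prefix lengths.
make_batch <- function(md, rows) {
  inst <- md$instances[rows, , drop = FALSE]
  N <- nrow(inst)
  kinds <- list()
  for (kd in md$kinds) {
    n <- inst[[paste0("n_", kd)]]
    Tn <- max(n, 0L)
    if (Tn == 0L) {
      kinds[[kd]] <- list(X = NULL, idx = NULL, n = n)
      next
    }
    mats <- vector("list", N)
    for (b in seq_len(N)) {
      if (n[b] > 0L) {
        mats[[b]] <- md$patients[[inst$patient_id[b]]][[kd]][
          seq_len(n[b]), , drop = FALSE
        ]
      }
    }
    X <- do.call(rbind, compact(mats))
    idx <- matrix(0L, N, Tn)
    at <- 0L
    for (b in seq_len(N)) {
      if (n[b] > 0L) {
        idx[b, seq_len(n[b])] <- at + seq_len(n[b])
        at <- at + n[b]
      }
    }
    kinds[[kd]] <- list(X = X, idx = idx, n = n)
  }
  dem <- do.call(rbind, lapply(inst$patient_id,
                               function(pid) md$patients[[pid]]$dem))
  list(
    kinds = kinds, dem = dem, t = inst$t_std,
    y = inst$y, score_kind = inst$score_kind, inst = inst
  )
}

# ---- last-value feature vectors ---------------------------------------------

# Raw last available value (unstandardised) of every feature of every
# time-related table under the eligibility rule, one row per instance.
# Shared by the feed-forward baseline and the similarity feature context.
raw_last_values <- function(registry, instances, lag_days = 15L) {
  out <- instances[c("patient_id", "target_index", "score_kind",
                     "target_date")]
  for (nm in c("clinical_measures", "medications", "prom")) {
    tbl <- arrange(registry[[nm]], .data$date)
    cols <- table_feature_cols(tbl)
    by_pid <- split(tbl, tbl$patient_id)
    for (cl in cols) {
      vals <- vector(if (is.numeric(tbl[[cl]])) "numeric" else "character",
                     nrow(out))
      vals[] <- NA
      for (i in seq_len(nrow(out))) {
        p <- by_pid[[out$patient_id[i]]]
        if (is.null(p)) next
        cutoff <- as.numeric(out$target_date[i]) - lag_days
        v <- p[[cl]][as.numeric(p$date) <= cutoff]
        v <- v[!is.na(v)]
        if (length(v) > 0L) vals[i] <- v[length(v)]
      }
      out[[cl]] <- vals
    }
  }
  dem <- registry$demographics
  out <- left_join(out, dem, by = "patient_id")
  out
}

# Encode a raw last-value table into the fixed-length numeric vector space of
# the feed-forward baseline / raw-space k-NN: standardised continuous values
# with availability flags, one-hot categoricals, plus standardised
# time-to-prediction.
encode_last_values <- function(raw, standardiser, instances, t_stats) {
  blocks <- list()
  for (nm in REGISTRY_TABLES) {
    spec <- standardiser[[nm]]
    have <- intersect(c(names(spec$cont), names(spec$cat)), names(raw))
    if (length(have) == 0L) next
    sub <- list(cont = spec$cont[intersect(names(spec$cont), have)],
                cat = spec$cat[intersect(names(spec$cat), have)])
    blocks[[nm]] <- encode_table(sub, raw, avail_flags = TRUE)
  }
  t_std <- (instances$t_days - t_stats$mean) / t_stats$sd
  t_std[is.na(t_std)] <- 0
  X <- do.call(cbind, c(blocks, list(t = matrix(t_std, ncol = 1,
                                                dimnames = list(NULL, "t")))))
  X
}

#' Last-value feature vectors for an instance set
#'
#' Builds, for every prediction instance, the fixed-length vector of the most
#' recent available value of each feature in the eligible history (respecting
#' the `lag_days` cutoff), standardised and imputed exactly as the network's
#' inputs, with availability flags, demographics and the standardised
#' time-to-prediction appended. This is the input representation of the
#' feed-forward baseline and of raw-space k-NN retrieval.
#'
#' @param registry A `das_registry`.
#' @param instances Instance tibble from [build_instances()].
#' @param standardiser A fitted `das_standardiser`.
#' @param t_stats List with `mean` and `sd` of the time-to-prediction on the
#'   training instances.
#' @param lag_days Eligibility cutoff in days.
#' @return A list: `X` (numeric matrix, one row per instance) and `raw`
#'   (the unencoded last values, used for similarity feature context).
#' @export
build_last_value_features <- function(registry, instances, standardiser,
                                      t_stats, lag_days = 15L) {
  raw <- raw_last_values(registry, instances, lag_days)
  X <- encode_last_values(raw, standardiser, instances, t_stats)
  list(X = X, raw = raw)
}
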