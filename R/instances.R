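# Prediction-instance construction and the patient-level train/test split.

#' Build prediction instances
#'
#' One instance is created per disease activity score recorded at a
#' patient's second, third, ... clinical measure. The eligible history of an
#' instance consists of the demographics plus every time-related event dated
#' at least `lag_days` before the target date (inclusive: an event exactly
#' `lag_days` before the target is eligible). A score used as the target at
#' one visit re-enters the history as an input feature for later targets.
#'
#' @param registry A (filtered) `das_registry`.
#' @param lag_days Minimum gap, in days, between an input event and the
#'   target clinical measure.
#' @return A tibble with one row per instance: `patient_id`, `target_index`
#'   (index of the target clinical measure within the patient's journey),
#'   `score_kind` (`"das28"` or `"asdas"`), `target_date`, `y` (true score),
#'   `t_days` (days from the last eligible event to the target, `NA` when no
#'   time-related event is eligible), per-kind eligible event counts
#'   `n_cm`, `n_med`, `n_prom`, and `n_prior_cms`.
#' @export
build_instances <- function(registry, lag_days = 15L) {
  cm <- arrange(registry$clinical_measures, .data$patient_id, .data$date)
  med <- registry$medications
  prom <- registry$prom

  cm_by <- split(cm, cm$patient_id)
  med_dates <- split(as.numeric(med$date), med$patient_id)
  prom_dates <- split(as.numeric(prom$date), prom$patient_id)

  rows <- lapply(cm_by, function(pcm) {
    n <- nrow(pcm)
    if (n < 2L) return(NULL)
    pid <- pcm$patient_id[1L]
    d <- as.numeric(pcm$date)
    md <- sort(med_dates[[pid]] %||% numeric(0))
    pd <- sort(prom_dates[[pid]] %||% numeric(0))
    res <- vector("list", n - 1L)
    for (v in 2:n) {
      kind <- if (!is.na(pcm$das28[v])) "das28" else
        if (!is.na(pcm$asdas[v])) "asdas" else NA_character_
      if (is.na(kind)) next
      cutoff <- d[v] - lag_days
      n_cm <- sum(d <= cutoff)
      n_med <- sum(md <= cutoff)
      n_prom <- sum(pd <= cutoff)
      last_ev <- suppressWarnings(max(c(d[d <= cutoff], md[md <= cutoff],
                                        pd[pd <= cutoff])))
      res[[v - 1L]] <- tibble(
        patient_id = pid, target_index = v, score_kind = kind,
        target_date = pcm$date[v],
        y = if (kind == "das28") pcm$das28[v] else pcm$asdas[v],
        t_days = if (is.finite(last_ev)) d[v] - last_ev else NA_real_,
        n_cm = n_cm, n_med = n_med, n_prom = n_prom,
        n_prior_cms = v - 1L
      )
    }
    bind_rows(res)
  })
  bind_rows(rows)
}

#' Stratified patient-level train/test split with CV folds
#'
#' Patients are stratified by their number of clinical measures;
#' `test_fraction` of each stratum is sampled as the test set and the
#' remaining patients receive cross-validation fold labels `1..n_folds`
#' within strata. All instances of a patient share its assignment. Strata
#' too small to fill the folds are merged with the nearest stratum by
#' clinical-measure count.
#'
#' @param registry A (filtered) `das_registry`.
#' @param test_fraction Fraction of patients per stratum held out for testing.
#' @param n_folds Number of cross-validation folds on the training patients.
#' @param seed Integer seed controlling the assignment.
#' @return A tibble `patient_id`, `n_cms`, `split` (`"train"`/`"test"`),
#'   `fold` (`NA` for test patients).
#' @export
stratified_split <- function(registry, test_fraction = 0.2, n_folds = 5L,
                             seed = 1L) {
  assert_fraction(test_fraction, "test_fraction")
  cm <- registry$clinical_measures
  if (nrow(cm) == 0L) abort("Empty cohort: no clinical measures.")
  counts <- cm |>
    count(.data$patient_id, name = "n_cms") |>
    arrange(.data$patient_id)

  # merge strata until each can populate the folds on its train side
  strata <- sort(unique(counts$n_cms))
  stratum_of <- setNames(strata, strata)
  repeat {
    sizes <- vapply(split(counts$n_cms, stratum_of[as.character(counts$n_cms)]),
                    length, integer(1))
    min_required <- n_folds / (1 - test_fraction)
    small <- names(sizes)[sizes < min_required]
    if (length(small) == 0L || length(sizes) == 1L) break
    s <- as.numeric(small[1L])
    others <- setdiff(as.numeric(unique(stratum_of)), s)
    nearest <- others[which.min(abs(others - s))]
    stratum_of[stratum_of == s] <- nearest
  }
  counts$stratum <- unname(stratum_of[as.character(counts$n_cms)])

  set.seed(seed)
  parts <- lapply(split(counts, counts$stratum), function(grp) {
    n <- nrow(grp)
    n_test <- round(n * test_fraction)
    idx <- sample.int(n)
    grp$split <- "train"
    grp$split[idx[seq_len(n_test)]] <- "test"
    tr <- which(grp$split == "train")
    grp$fold <- NA_integer_
    grp$fold[tr[sample.int(length(tr))]] <-
      rep_len(seq_len(n_folds), length(tr))
    grp
  })
  bind_rows(parts) |>
    select("patient_id", "n_cms", "split", "fold") |>
    arrange(.data$patient_id)
}
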