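# Loading the four registry tables and the record/patient-level filters
# applied before instance construction.

REGISTRY_TABLES <- c("demographics", "clinical_measures", "medications", "prom")

as_registry <- function(tables) {
  structure(tables, class = "das_registry")
}

#' Load registry tables from a directory of CSV files
#'
#' Reads `demographics.csv`, `clinical_measures.csv`, `medications.csv` and
#' `prom.csv` (and `ground_truth.csv` if present) as written by
#' [write_registry()]. Dates are parsed as `Date`; rows of time-related
#' tables whose date fails to parse are kept but flagged — they are removed
#' by [filter_patients()].
#'
#' @param dir Directory containing the CSV files.
#' @return A `das_registry` list of tibbles.
#' @export
load_registry <- function(dir) {
  paths <- file.path(dir, paste0(REGISTRY_TABLES, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(paste0("Missing registry file(s): ",
                 paste(basename(paths[missing]), collapse = ", ")))
  }
  tables <- lapply(paths, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  names(tables) <- REGISTRY_TABLES
  for (nm in REGISTRY_TABLES) {
    if (!"patient_id" %in% names(tables[[nm]])) {
      abort(sprintf("Table '%s' lacks a patient_id column.", nm))
    }
    tables[[nm]]$patient_id <- as.character(tables[[nm]]$patient_id)
    # all-missing numeric columns are indistinguishable from logicals in CSV
    for (cl in setdiff(names(tables[[nm]]), c("patient_id", "date"))) {
      if (is.logical(tables[[nm]][[cl]]) && all(is.na(tables[[nm]][[cl]]))) {
        tables[[nm]][[cl]] <- as.numeric(tables[[nm]][[cl]])
      }
    }
    for (cl in intersect(score_cols, names(tables[[nm]]))) {
      tables[[nm]][[cl]] <- as.numeric(tables[[nm]][[cl]])
    }
    if (nm != "demographics") {
      d <- tables[[nm]]$date
      if (!inherits(d, "Date")) {
        tables[[nm]]$date <- as.Date(as.character(d), format = "%Y-%m-%d")
      }
    }
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    tables$ground_truth <- readr::read_csv(gt_path, show_col_types = FALSE,
                                           progress = FALSE)
  }
  as_registry(tables)
}

score_cols <- c("das28", "asdas")

#' Apply the registry inclusion filters
#'
#' Removes, in this order: time-related records with missing dates; clinical
#' measures recording neither DAS28 nor ASDAS; patients with fewer than
#' `min_cms` clinical measures carrying distinct disease activity values
#' (at least two different values among at least `min_cms` scored visits);
#' and patients without any medication information. All tables are then
#' restricted to the surviving patients. The operation is idempotent.
#'
#' @param registry A `das_registry`.
#' @param min_cms Minimum number of scored clinical measures per patient.
#' @return The filtered `das_registry`.
#' @export
filter_patients <- function(registry, min_cms = 3L) {
  reg <- registry
  for (nm in c("clinical_measures", "medications", "prom")) {
    reg[[nm]] <- filter(reg[[nm]], !is.na(.data$date))
  }
  cm <- reg$clinical_measures
  has_score <- rowSums(!is.na(cm[score_cols])) > 0
  cm <- cm[has_score, , drop = FALSE]
  reg$clinical_measures <- cm

  score_val <- dplyr::coalesce(cm$das28, cm$asdas)
  per_patient <- tibble(patient_id = cm$patient_id, score = score_val) |>
    group_by(.data$patient_id) |>
    summarise(n_cms = n(), n_vals = n_distinct(.data$score),
              .groups = "drop")
  ok_cm <- per_patient$patient_id[
    per_patient$n_cms >= min_cms & per_patient$n_vals >= 2L
  ]
  ok_med <- unique(reg$medications$patient_id)
  keep <- intersect(intersect(ok_cm, ok_med),
                    reg$demographics$patient_id)

  for (nm in REGISTRY_TABLES) {
    reg[[nm]] <- filter(reg[[nm]], .data$patient_id %in% keep)
  }
  if (!is.null(reg$ground_truth)) {
    reg$ground_truth <- filter(reg$ground_truth, .data$patient_id %in% keep)
  }
  reg
}

#' Restrict medications to the most-prescribed drugs
#'
#' Keeps the records of the smallest set of most frequently prescribed drugs
#' that together cover at least `coverage` of all medication records
#' (ties in frequency resolved by drug name for determinism).
#'
#' @param registry A `das_registry`.
#' @param coverage Fraction of medication records the kept drugs must cover.
#' @return The registry with the medication table restricted.
#' @export
select_medications <- function(registry, coverage = 0.90) {
  med <- registry$medications
  if (nrow(med) == 0L) return(registry)
  if (!"drug" %in% names(med)) abort("Medication table lacks a 'drug' column.")
  freq <- med |>
    count(.data$drug, sort = TRUE) |>
    arrange(desc(.data$n), .data$drug) |>
    mutate(cum = cumsum(.data$n) / sum(.data$n))
  n_keep <- which(freq$cum >= coverage - 1e-12)[1L]
  kept <- freq$drug[seq_len(n_keep)]
  registry$medications <- filter(med, .data$drug %in% kept)
  registry
}
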