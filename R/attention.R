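# Aggregation of attention records over a test set: global weights by
# history length and by clinical-improvement status, local clinical-measure
# weights by position relative to the target.

# last prior same-kind score for every instance (no eligibility cutoff:
# improvement is defined relative to the immediately preceding recorded score)
last_prior_score <- function(registry, instances) {
  cm <- arrange(registry$clinical_measures, .data$date)
  cm_by <- split(cm, cm$patient_id)
  out <- rep(NA_real_, nrow(instances))
  for (i in seq_len(nrow(instances))) {
    p <- cm_by[[instances$patient_id[i]]]
    vals <- p[[instances$score_kind[i]]]
    prior <- vals[as.numeric(p$date) < as.numeric(instances$target_date[i]) &
                    !is.na(vals)]
    if (length(prior)) out[i] <- prior[length(prior)]
  }
  out
}

#' Summarise attention weights over a set of instances
#'
#' Computes mean global attention weights per information source, stratified
#' by the number of already-predicted targets (history length) and by
#' improvement status — an instance counts as improved when its true score is
#' at least `improve_frac` lower than the last prior recorded score of the
#' same kind. Local clinical-measure weights are summarised by position
#' counted backwards from the target (1 = most recent eligible event).
#'
#' @param fit A fitted `dasnet`.
#' @param registry The registry to evaluate on.
#' @param patients Patient ids to include (e.g. the test split).
#' @param improve_frac Relative improvement threshold.
#' @param max_targets History lengths above this are pooled into one stratum.
#' @return An object of class `das_attention_summary`: tibbles
#'   `global_by_targets`, `global_by_improvement`, `local_by_position`.
#' @export
summarise_attention <- function(fit, registry, patients = NULL,
                                improve_frac = 0.2, max_targets = 6L) {
  attn <- dasnet_attention(fit, registry, patients)
  instances <- attn$global |>
    distinct(.data$patient_id, .data$target_index, .data$score_kind,
             .data$n_prior_cms, .data$y_true)
  inst_full <- filter(build_instances(registry, fit$lag_days),
                      !is.na(.data$y))
  inst_full <- semi_join(
    inst_full, instances,
    by = c("patient_id", "target_index", "score_kind")
  )
  prev <- last_prior_score(registry, inst_full)
  improvement <- tibble(
    patient_id = inst_full$patient_id,
    target_index = inst_full$target_index,
    improved = !is.na(prev) & prev > 0 &
      (prev - inst_full$y) / prev >= improve_frac
  )

  glob <- attn$global |>
    left_join(improvement, by = c("patient_id", "target_index")) |>
    mutate(
      n_targets = pmin(.data$target_index - 1L, max_targets),
      n_targets = if_else(.data$n_targets >= max_targets,
                          paste0(max_targets, "+"),
                          as.character(.data$n_targets))
    )
  global_by_targets <- glob |>
    group_by(.data$score_kind, .data$n_targets, .data$source) |>
    summarise(mean_weight = mean(.data$weight), n = n() , .groups = "drop")
  global_by_improvement <- glob |>
    filter(!is.na(.data$improved)) |>
    group_by(.data$score_kind, .data$improved, .data$source) |>
    summarise(mean_weight = mean(.data$weight), n = n(), .groups = "drop")
  local_by_position <- attn$local |>
    filter(.data$kind == if ("cm" %in% attn$local$kind) "cm" else
      unique(attn$local$kind)[1L]) |>
    group_by(.data$score_kind, .data$reverse_position) |>
    summarise(mean_weight = mean(.data$weight), n = n(), .groups = "drop")

  structure(
    list(global_by_targets = global_by_targets,
         global_by_improvement = global_by_improvement,
         local_by_position = local_by_position,
         improve_frac = improve_frac),
    class = "das_attention_summary"
  )
}

#' @export
print.das_attention_summary <- function(x, ...) {
  cat("<das_attention_summary>\n")
  cat("Global attention by number of predicted targets:\n")
  print(tidyr::pivot_wider(x$global_by_targets,
                           names_from = "source",
                           values_from = "mean_weight", id_cols = c("score_kind", "n_targets")))
  invisible(x)
}
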