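# Feature standardisation and encoding, fitted on training patients only.
#
# Continuous features are z-scored with the population (1/n) standard
# deviation and mean-imputed (0 after standardisation) with an availability
# flag appended; categorical features are one-hot encoded with an explicit
# "(missing)" category. Fitting on the training split only is part of the
# no-leakage contract: the returned object carries everything needed to
# encode unseen patients.

MISSING_LEVEL <- "(missing)"

table_feature_cols <- function(tbl) {
  setdiff(names(tbl), c("patient_id", "date"))
}

#' Fit a feature standardiser on training patients
#'
#' Computes, per registry table and feature, the training mean and population
#' standard deviation (continuous features) or the observed category levels
#' (categorical features). Only records belonging to `patient_ids` are used,
#' so no information from held-out patients enters the encoding.
#'
#' @param registry A `das_registry`.
#' @param patient_ids Patients whose records the fit may see (default: all).
#' @return An object of class `das_standardiser`.
#' @export
fit_standardiser <- function(registry, patient_ids = NULL) {
  out <- list()
  for (nm in REGISTRY_TABLES) {
    tbl <- registry[[nm]]
    if (!is.null(patient_ids)) {
      tbl <- filter(tbl, .data$patient_id %in% patient_ids)
    }
    cols <- table_feature_cols(registry[[nm]])
    spec <- list(cont = list(), cat = list())
    for (cl in cols) {
      v <- tbl[[cl]]
      if (is.numeric(v)) {
        ok <- v[!is.na(v)]
        if (length(ok) == 0L) {
          spec$cont[[cl]] <- list(mean = 0, sd = 1, constant = TRUE)
        } else {
          m <- mean(ok)
          s <- sqrt(mean((ok - m)^2))
          spec$cont[[cl]] <- list(
            mean = m, sd = if (s > 0) s else 1, constant = s == 0
          )
        }
      } else {
        lev <- sort(unique(as.character(v[!is.na(v)])))
        spec$cat[[cl]] <- c(lev, MISSING_LEVEL)
      }
    }
    out[[nm]] <- spec
  }
  structure(out, class = "das_standardiser")
}

# encode one table into a numeric matrix: z-scored continuous columns with
# availability flags, one-hot categorical columns with an explicit missing
# level. Column layout is fully determined by the standardiser.
encode_table <- function(std_spec, tbl, avail_flags = TRUE) {
  n <- nrow(tbl)
  blocks <- list()
  for (cl in names(std_spec$cont)) {
    v <- if (cl %in% names(tbl)) as.numeric(tbl[[cl]]) else rep(NA_real_, n)
    avail <- as.numeric(!is.na(v))
    z <- (v - std_spec$cont[[cl]]$mean) / std_spec$cont[[cl]]$sd
    z[is.na(z)] <- 0
    blocks[[cl]] <- matrix(z, ncol = 1,
                           dimnames = list(NULL, cl))
    if (avail_flags) {
      blocks[[paste0(cl, "_avail")]] <- matrix(
        avail, ncol = 1, dimnames = list(NULL, paste0(cl, "_avail"))
      )
    }
  }
  for (cl in names(std_spec$cat)) {
    lev <- std_spec$cat[[cl]]
    v <- if (cl %in% names(tbl)) as.character(tbl[[cl]]) else
      rep(NA_character_, n)
    v[is.na(v) | !(v %in% lev)] <- MISSING_LEVEL
    oh <- matrix(0, n, length(lev),
                 dimnames = list(NULL, paste0(cl, "=", lev)))
    oh[cbind(seq_len(n), match(v, lev))] <- 1
    blocks[[cl]] <- oh
  }
  if (length(blocks) == 0L) return(matrix(0, n, 0))
  do.call(cbind, blocks)
}

#' Encode registry tables with a fitted standardiser
#'
#' Applies the transformation fitted by [fit_standardiser()] to (possibly
#' different) registry tables. Missing continuous entries become 0 (the
#' training mean) with availability flag 0; categories unseen in training
#' map to the explicit missing level.
#'
#' @param standardiser A `das_standardiser`.
#' @param registry A `das_registry`.
#' @return A list with one element per table: `patient_id`, `date` (except
#'   demographics) and the encoded numeric matrix `X`.
#' @export
apply_standardiser <- function(standardiser, registry) {
  stopifnot(inherits(standardiser, "das_standardiser"))
  out <- list()
  for (nm in REGISTRY_TABLES) {
    tbl <- registry[[nm]]
    if (nm != "demographics") {
      ord <- order(tbl$date) # stable: ties keep record order in file
      tbl <- tbl[ord, , drop = FALSE]
    }
    X <- encode_table(standardiser[[nm]], tbl,
                      avail_flags = nm != "demographics")
    out[[nm]] <- list(
      patient_id = tbl$patient_id,
      date = if (nm == "demographics") NULL else tbl$date,
      X = X
    )
  }
  out
}
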