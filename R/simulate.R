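# Synthetic inflammatory-arthritis registry generator.
#
# A known AR(1) latent disease-activity process drives everything that is
# observed: the recorded disease activity scores are clipped affine
# transforms of the latent state, medications shift the trajectory while
# active, patient-reported outcomes are noisy monotone transforms of it.
# The generator therefore provides ground truth (latent states, Bayes-optimal
# one-step error) against which the forecasting pipeline can be validated.

DRUG_CATALOG <- tibble::tribble(
  ~drug,           ~category,  ~weight,
  "methotrexate",  "csDMARD",  0.30,
  "adalimumab",    "bDMARD",   0.16,
  "etanercept",    "bDMARD",   0.13,
  "leflunomide",   "csDMARD",  0.09,
  "tofacitinib",   "tsDMARD",  0.08,
  "secukinumab",   "bDMARD",   0.07,
  "sulfasalazine", "csDMARD",  0.06,
  "rituximab",     "bDMARD",   0.04,
  "golimumab",     "bDMARD",   0.03,
  "abatacept",     "bDMARD",   0.02,
  "hydroxychloroquine", "csDMARD", 0.015,
  "baricitinib",   "tsDMARD",  0.005
)

#' Configuration of the synthetic registry generator
#'
#' Defines the cohort size and the parameters of the latent AR(1) disease
#' process used to simulate registry tables. The latent activity of patient
#' \eqn{p} at visit \eqn{i+1} follows
#' \deqn{a_{i+1} = \rho a_i + \mathrm{med}_{i+1} + \mathrm{cov}_p + \epsilon_i,
#'   \quad \epsilon_i \sim N(0, \sigma^2),}
#' where \eqn{\mathrm{med}} is `med_effect` times the number of active
#' disease-modifying drugs at the visit and \eqn{\mathrm{cov}_p} collects the
#' demographic covariate effects (including the intercept). DAS28 is the
#' latent state clipped to \eqn{[0, 10]}; ASDAS is an affine rescaling
#' clipped to \eqn{[0, 6]}.
#'
#' @param n_patients Number of patients in the cohort.
#' @param visit_rate Mean number of clinical visits per year (homogeneous
#'   Poisson process).
#' @param followup_years Length of follow-up in years.
#' @param subtype_probs Named probabilities over the arthritis subtypes
#'   `RA`, `axSpA`, `PsA`, `UA`; must sum to 1. RA patients record DAS28,
#'   axSpA patients ASDAS, PsA/UA patients one of the two (chosen once per
#'   patient).
#' @param ar_coefficient Autoregressive coefficient \eqn{\rho \in [0, 1)}
#'   (`1` is tolerated only with `noise_sd = 0`, the degenerate constant
#'   trajectory).
#' @param noise_sd Innovation standard deviation \eqn{\sigma} in score units.
#' @param med_effect Shift in latent activity per active drug (negative for
#'   effective treatment).
#' @param covariate_effects Named numeric vector with elements `intercept`,
#'   `age` (per standard deviation of age) and `sexM`.
#' @param missing_rate Probability that any one auxiliary feature value
#'   (labs, joint counts, patient-reported measures) is missing.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce identical registries.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_registry()]
#' @export
sim_config <- function(n_patients = 600,
                       visit_rate = 3,
                       followup_years = 4,
                       subtype_probs = c(RA = 0.45, axSpA = 0.30,
                                         PsA = 0.15, UA = 0.10),
                       ar_coefficient = 0.8,
                       noise_sd = 0.5,
                       med_effect = -0.5,
                       covariate_effects = c(intercept = 0.8, age = 0.1,
                                             sexM = -0.1),
                       missing_rate = 0.1,
                       seed = 1L) {
  assert_positive(n_patients, "n_patients")
  assert_positive(visit_rate, "visit_rate")
  assert_positive(followup_years, "followup_years")
  if (!all(c("RA", "axSpA", "PsA", "UA") %in% names(subtype_probs))) {
    abort("`subtype_probs` must name RA, axSpA, PsA and UA.")
  }
  if (abs(sum(subtype_probs) - 1) > 1e-9) {
    abort("`subtype_probs` must sum to 1.")
  }
  if (!is.finite(ar_coefficient) || ar_coefficient < 0 || ar_coefficient > 1 ||
      (ar_coefficient == 1 && noise_sd > 0)) {
    abort("`ar_coefficient` must lie in [0, 1).")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a non-negative finite number.")
  }
  if (!is.finite(med_effect)) abort("`med_effect` must be finite.")
  if (!all(is.finite(covariate_effects))) {
    abort("`covariate_effects` must all be finite.")
  }
  assert_fraction(missing_rate, "missing_rate")
  structure(
    list(
      n_patients = as.integer(n_patients), visit_rate = visit_rate,
      followup_years = followup_years,
      subtype_probs = subtype_probs[c("RA", "axSpA", "PsA", "UA")],
      ar_coefficient = ar_coefficient, noise_sd = noise_sd,
      med_effect = med_effect, covariate_effects = covariate_effects,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients,",
      x$followup_years, "years follow-up,",
      "rho =", x$ar_coefficient, ", sigma =", x$noise_sd, "\n")
  invisible(x)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

latent_to_das28 <- function(a) clip(a, 0, 10)
latent_to_asdas <- function(a) clip(0.6 * a, 0, 6)

maybe_missing <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) return(x)
  x[runif(length(x)) < rate] <- NA
  x
}

#' Simulate one patient journey
#'
#' Draws a single patient's demographics, visit schedule, latent disease
#' trajectory, medication episodes, clinical measures and patient-reported
#' outcomes from the generator defined by `config`. Uses the current RNG
#' state; [simulate_registry()] seeds it once per cohort.
#'
#' @param config A [sim_config()].
#' @param patient_id Identifier string for the patient.
#' @return A list with elements `demographics`, `clinical_measures`,
#'   `medications`, `prom` (tibbles in the registry schema) and
#'   `ground_truth` (per-visit latent state and realised effect terms).
#' @export
simulate_patient <- function(config, patient_id) {
  rho <- config$ar_coefficient
  sigma <- config$noise_sd
  ce <- config$covariate_effects

  subtype <- sample(names(config$subtype_probs), 1L,
                    prob = config$subtype_probs)
  score_kind <- switch(subtype,
    RA = "das28", axSpA = "asdas",
    sample(c("das28", "asdas"), 1L)
  )
  age <- round(rnorm(1L, 55, 13), 1)
  sex <- sample(c("F", "M"), 1L, prob = c(0.7, 0.3))
  cov_term <- unname(ce["intercept"] +
                       ce["age"] * (age - 55) / 13 +
                       ce["sexM"] * (sex == "M"))

  baseline <- as.Date("2010-01-01") + floor(runif(1L, 0, 8 * 365.25))
  n_visits <- rpois(1L, config$visit_rate * config$followup_years)
  visit_days <- sort(floor(runif(n_visits, 0, config$followup_years * 365.25)))
  visit_days <- unique(visit_days) # strictly increasing, day resolution
  n_visits <- length(visit_days)
  dates <- baseline + visit_days

  # medication episodes: start at a random visit, persist until a random
  # later visit (or ongoing). Every patient has at least one episode.
  n_epi <- 1L + rpois(1L, 0.7)
  med_rows <- list()
  episodes <- list()
  for (e in seq_len(n_epi)) {
    drug <- sample(DRUG_CATALOG$drug, 1L, prob = DRUG_CATALOG$weight)
    cat_e <- DRUG_CATALOG$category[match(drug, DRUG_CATALOG$drug)]
    if (n_visits == 0L) {
      start_day <- 0
      stop_day <- Inf
    } else {
      start_idx <- sample.int(n_visits, 1L)
      start_day <- visit_days[start_idx]
      stop_day <- if (start_idx < n_visits && runif(1L) < 0.6) {
        visit_days[start_idx + sample.int(n_visits - start_idx, 1L)]
      } else {
        Inf # ongoing at end of follow-up
      }
    }
    episodes[[e]] <- c(start = start_day, stop = stop_day)
    med_rows[[length(med_rows) + 1L]] <- tibble(
      patient_id = patient_id, date = baseline + start_day,
      drug = drug, category = cat_e, event = "start"
    )
    if (is.finite(stop_day)) {
      med_rows[[length(med_rows) + 1L]] <- tibble(
        patient_id = patient_id, date = baseline + stop_day,
        drug = drug, category = cat_e, event = "stop"
      )
    }
  }
  n_active <- function(day) {
    sum(vapply(episodes, function(ep) day >= ep["start"] && day < ep["stop"],
               logical(1)))
  }

  # latent AR(1) trajectory at visit times
  latent <- numeric(n_visits)
  med_terms <- numeric(n_visits)
  if (n_visits > 0L) {
    med_terms[1L] <- config$med_effect * n_active(visit_days[1L])
    stat_mean <- if (rho < 1) {
      (cov_term + med_terms[1L]) / (1 - rho)
    } else {
      3.5 + cov_term + med_terms[1L]
    }
    stat_sd <- if (rho < 1 && sigma > 0) sigma / sqrt(1 - rho^2) else 0
    latent[1L] <- rnorm(1L, stat_mean, stat_sd)
    if (n_visits > 1L) {
      for (i in 2:n_visits) {
        med_terms[i] <- config$med_effect * n_active(visit_days[i])
        latent[i] <- rho * latent[i - 1L] + cov_term + med_terms[i] +
          rnorm(1L, 0, sigma)
      }
    }
  }

  das28 <- if (score_kind == "das28") latent_to_das28(latent) else
    rep(NA_real_, n_visits)
  asdas <- if (score_kind == "asdas") latent_to_asdas(latent) else
    rep(NA_real_, n_visits)

  mr <- config$missing_rate
  cm <- tibble(
    patient_id = patient_id, date = dates,
    das28 = das28, asdas = asdas,
    crp = maybe_missing(round(exp(0.30 * latent + rnorm(n_visits, 0, 0.30)), 2), mr),
    bsr = maybe_missing(round(clip(10 + 4 * latent + rnorm(n_visits, 0, 5), 1, 120), 1), mr),
    n_swollen_joints = maybe_missing(round(clip(2.2 * latent + rnorm(n_visits, 0, 2), 0, 28)), mr),
    n_painful_joints = maybe_missing(round(clip(2.6 * latent + rnorm(n_visits, 0, 2.5), 0, 28)), mr)
  )

  # PROMs: recorded at ~90% of visits, noisy monotone transforms of latent
  has_prom <- runif(n_visits) < 0.9
  lat_p <- latent[has_prom]
  np <- sum(has_prom)
  stiff_levels <- c("none", "less_than_1h", "1_to_4_hours", "all_day")
  stiff_raw <- lat_p + rnorm(np, 0, 1)
  prom <- tibble(
    patient_id = patient_id, date = dates[has_prom],
    radai_score = maybe_missing(round(clip(lat_p + rnorm(np, 0, 0.8), 0, 10), 1), mr),
    pain_level = maybe_missing(round(clip(lat_p + rnorm(np, 0, 1.2), 0, 10), 1), mr),
    morning_stiffness = maybe_missing(
      stiff_levels[findInterval(stiff_raw, c(-Inf, 2.5, 4.5, 6.5)) ], mr
    )
  )

  list(
    demographics = tibble(
      patient_id = patient_id, age = age, sex = sex, diagnosis = subtype
    ),
    clinical_measures = cm,
    medications = bind_rows(med_rows),
    prom = prom,
    ground_truth = tibble(
      patient_id = patient_id, visit_index = seq_len(n_visits),
      date = dates, latent = latent, med_term = med_terms,
      cov_term = rep(cov_term, n_visits), score_kind = rep(score_kind, n_visits)
    )
  )
}

#' Simulate a registry cohort
#'
#' Generates the four registry tables (demographics, clinical measures,
#' medications, patient-reported outcomes) together with the generator's
#' ground truth for `config$n_patients` patients.
#'
#' @param config A [sim_config()].
#' @return An object of class `das_registry`: a list of tibbles
#'   `demographics`, `clinical_measures`, `medications`, `prom`,
#'   `ground_truth`, plus the attribute `bayes_mse` (\eqn{\sigma^2}, the
#'   mean squared error of the Bayes-optimal one-step predictor of the
#'   latent state).
#' @examples
#' reg <- simulate_registry(sim_config(n_patients = 20, seed = 7))
#' nrow(reg$demographics)
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("P%04d", seq_len(config$n_patients))
  sims <- lapply(ids, function(id) simulate_patient(config, id))
  out <- list(
    demographics = bind_rows(lapply(sims, `[[`, "demographics")),
    clinical_measures = bind_rows(lapply(sims, `[[`, "clinical_measures")),
    medications = bind_rows(lapply(sims, `[[`, "medications")),
    prom = bind_rows(lapply(sims, `[[`, "prom")),
    ground_truth = bind_rows(lapply(sims, `[[`, "ground_truth"))
  )
  structure(out, class = "das_registry",
            bayes_mse = config$noise_sd^2, config = config)
}

#' @export
print.das_registry <- function(x, ...) {
  cat("<das_registry>", nrow(x$demographics), "patients,",
      nrow(x$clinical_measures), "clinical measures,",
      nrow(x$medications), "medication events,",
      nrow(x$prom), "PROM records\n")
  invisible(x)
}

#' Write registry tables to CSV files
#'
#' Serialises the registry tables as plain CSV with ISO-8601 dates, the
#' on-disk interchange format of the package. [load_registry()] reads the
#' files back losslessly.
#'
#' @param registry A `das_registry` or a plain list of the four tables.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("demographics", "clinical_measures", "medications", "prom")
  if (!is.null(registry$ground_truth)) tables <- c(tables, "ground_truth")
  paths <- vapply(tables, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(registry[[nm]], path, na = "")
    path
  }, character(1))
  invisible(paths)
}
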