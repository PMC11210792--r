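# Shared fixtures and independent oracle implementations used across tests.
# The oracles are deliberately naive (explicit loops, exhaustive search) and
# never share code with the package internals they validate.

# ---- small simulated cohorts -------------------------------------------------

small_config <- function(n = 40L, seed = 7L, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

small_cohort <- function(n = 40L, seed = 7L, ...) {
  simulate_registry(small_config(n, seed, ...)) |>
    filter_patients() |>
    select_medications()
}

# a small trained model shared by similarity/attention/evaluation tests;
# trained once per session and cached
.fit_cache <- new.env(parent = emptyenv())

cached_small_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache$fit)
  reg <- small_cohort(n = 60L, seed = 21L)
  sp <- stratified_split(reg, seed = 21L)
  fit <- dasnet(
    reg, sp, config = dasnet_config(q = 6L, encoder_hidden = c(8L, 8L),
                                    head_hidden = c(8L, 8L)),
    control = dasnet_control(epochs = 6L, patience = 6L, seed = 21L)
  )
  .fit_cache$fit <- list(reg = reg, sp = sp, fit = fit)
  .fit_cache$fit
}

# ---- hand-built toy registry covering every preprocessing filter case --------

toy_registry <- function() {
  d <- function(x) as.Date(x)
  demographics <- tibble::tibble(
    patient_id = paste0("T", 1:8),
    age = c(50, 60, 45, 55, 65, 40, 52, 58),
    sex = c("F", "M", "F", "F", "M", "F", "M", "F"),
    diagnosis = c("RA", "RA", "axSpA", "RA", "PsA", "RA", "axSpA", "UA")
  )
  cm <- dplyr::bind_rows(
    # T1: 4 CMs, distinct DAS28 values, has medication -> retained
    tibble::tibble(patient_id = "T1",
                   date = d(c("2020-01-01", "2020-03-01", "2020-06-01",
                              "2020-09-01")),
                   das28 = c(4.0, 3.5, 3.0, 2.5), asdas = NA_real_),
    # T2: only 2 CMs -> removed (fewer than three)
    tibble::tibble(patient_id = "T2",
                   date = d(c("2020-01-01", "2020-05-01")),
                   das28 = c(4.0, 3.0), asdas = NA_real_),
    # T3: 3 CMs but all ASDAS values identical -> removed (not distinct)
    tibble::tibble(patient_id = "T3",
                   date = d(c("2020-01-01", "2020-04-01", "2020-08-01")),
                   das28 = NA_real_, asdas = c(2.5, 2.5, 2.5)),
    # T4: 3 distinct-DAS CMs but no medication rows -> removed
    tibble::tibble(patient_id = "T4",
                   date = d(c("2020-01-01", "2020-04-01", "2020-08-01")),
                   das28 = c(5, 4, 3), asdas = NA_real_),
    # T5: 4 CMs, one lacking both scores (dropped as record), still 3
    # distinct-DAS CMs -> retained
    tibble::tibble(patient_id = "T5",
                   date = d(c("2020-01-01", "2020-03-01", "2020-06-01",
                              "2020-09-01")),
                   das28 = c(4.4, NA, 3.2, 2.1), asdas = NA_real_),
    # T6: 3 scored CMs but one has a missing date (dropped) -> only 2 left
    # -> removed
    tibble::tibble(patient_id = "T6",
                   date = d(c("2020-01-01", NA, "2020-08-01")),
                   das28 = c(5.0, 4.0, 3.0), asdas = NA_real_),
    # T7: 3 distinct ASDAS CMs with medication -> retained
    tibble::tibble(patient_id = "T7",
                   date = d(c("2020-01-01", "2020-05-01", "2020-10-01")),
                   das28 = NA_real_, asdas = c(3.0, 2.4, 1.8)),
    # T8: CMs lacking both scores only -> removed
    tibble::tibble(patient_id = "T8",
                   date = d(c("2020-01-01", "2020-04-01", "2020-08-01")),
                   das28 = NA_real_, asdas = NA_real_)
  )
  cm$crp <- 5
  medications <- tibble::tibble(
    patient_id = c("T1", "T2", "T3", "T5", "T6", "T7", "T8", "T7"),
    date = d(c("2020-01-01", "2020-01-01", "2020-01-01", "2020-01-15",
               "2020-01-01", "2020-02-01", "2020-01-01", NA)),
    drug = c("methotrexate", "methotrexate", "adalimumab", "methotrexate",
             "etanercept", "adalimumab", "methotrexate", "rituximab"),
    category = c("csDMARD", "csDMARD", "bDMARD", "csDMARD", "bDMARD",
                 "bDMARD", "csDMARD", "bDMARD"),
    event = "start"
  )
  prom <- tibble::tibble(
    patient_id = c("T1", "T5", "T7"),
    date = d(c("2020-01-01", "2020-01-01", "2020-01-01")),
    radai_score = c(4, 5, 3), pain_level = c(3, 6, 2),
    morning_stiffness = c("none", "all_day", "less_than_1h")
  )
  structure(list(demographics = demographics, clinical_measures = cm,
                 medications = medications, prom = prom),
            class = "das_registry")
}

# ---- independent oracles -----------------------------------------------------

# triple-loop evaluation of the multi-task batch loss
oracle_eq1 <- function(batches) {
  total <- 0
  for (b in batches) {
    if (nrow(b$targets) == 0L) next
    acc <- 0
    for (p in unique(b$targets$patient)) {
      sub <- b$targets[b$targets$patient == p, ]
      for (v in seq_len(nrow(sub))) {
        acc <- acc + (sub$pred[v] - sub$y[v])^2
      }
    }
    total <- total + acc / nrow(b$targets)
  }
  total
}

# exhaustive L1 nearest neighbours
oracle_knn <- function(R_train, e, k) {
  d <- apply(R_train, 1L, function(r) sum(abs(r - e)))
  ord <- order(d)[seq_len(k)]
  list(neighbours = ord, distances = d[ord])
}

# direct AAD computation
oracle_aad <- function(x_test, x_train, nn, sd_ref) {
  devs <- c()
  for (i in seq_along(x_test)) {
    if (is.na(x_test[i])) next
    nv <- x_train[nn[i, ]]
    nv <- nv[!is.na(nv)]
    if (!length(nv)) next
    devs <- c(devs, abs(x_test[i] - sum(nv) / length(nv)))
  }
  a <- sum(devs) / length(devs)
  c(aad = a, aad_std = a / sd_ref)
}

# direct adjusted-probability computation for one category
oracle_adjusted <- function(x_test, x_train, nn, cat) {
  num <- 0
  den <- 0
  for (i in seq_along(x_test)) {
    if (is.na(x_test[i]) || x_test[i] != cat) next
    nv <- x_train[nn[i, ]]
    nv <- nv[!is.na(nv)]
    num <- num + sum(nv == cat)
    den <- den + length(nv)
  }
  num / den
}

# random parameter tree for a tiny configuration
tiny_params <- function(seed = 5L, q = 3L,
                        dims = list(cm = 4L, med = 3L, prom = 2L, dem = 3L)) {
  set.seed(seed)
  cfg <- dasnet_config(q = q, encoder_hidden = c(4L, 4L),
                       head_hidden = c(4L, 4L))
  list(params = dasnet:::init_dasnet_params(cfg, dims), config = cfg,
       dims = dims)
}

# hand-assembled forward batch in the internal format
tiny_batch <- function(seed = 6L, N = 5L,
                       n_cm = c(3L, 0L, 2L, 1L, 4L),
                       n_med = c(1L, 2L, 0L, 0L, 1L),
                       n_prom = c(0L, 1L, 2L, 1L, 0L),
                       dims = list(cm = 4L, med = 3L, prom = 2L, dem = 3L)) {
  set.seed(seed)
  mk <- function(n, p) if (sum(n) > 0) matrix(rnorm(sum(n) * p), sum(n), p)
  idx_of <- function(n) {
    Tn <- max(n)
    if (Tn == 0L) return(NULL)
    idx <- matrix(0L, length(n), Tn)
    at <- 0L
    for (b in seq_along(n)) {
      if (n[b] > 0L) {
        idx[b, seq_len(n[b])] <- at + seq_len(n[b])
        at <- at + n[b]
      }
    }
    idx
  }
  list(
    kinds = list(
      cm = list(X = mk(n_cm, dims$cm), idx = idx_of(n_cm), n = n_cm),
      med = list(X = mk(n_med, dims$med), idx = idx_of(n_med), n = n_med),
      prom = list(X = mk(n_prom, dims$prom), idx = idx_of(n_prom), n = n_prom)
    ),
    dem = matrix(rnorm(N * dims$dem), N, dims$dem),
    t = rnorm(N),
    y = rnorm(N),
    score_kind = rep(c("das28", "asdas"), length.out = N)
  )
}

# hand-assembled embedding index for retrieval/importance oracles
manual_index <- function(R_train, R_test, y_train, y_test,
                         kind_train = NULL, kind_test = NULL,
                         ctx_train = NULL, ctx_test = NULL) {
  n_tr <- nrow(R_train)
  n_te <- nrow(R_test)
  kind_train <- kind_train %||% rep("das28", n_tr)
  kind_test <- kind_test %||% rep("das28", n_te)
  keys <- function(n, kind, y, pfx) tibble::tibble(
    patient_id = sprintf("%s%03d", pfx, seq_len(n)),
    target_index = 2L, score_kind = kind,
    target_date = as.Date("2021-01-01"), n_prior_cms = 1L, y_true = y
  )
  structure(list(
    train = keys(n_tr, kind_train, y_train, "TR"),
    test = keys(n_te, kind_test, y_test, "TE"),
    R_train = R_train, R_test = R_test,
    context_train = ctx_train %||% keys(n_tr, kind_train, y_train, "TR"),
    context_test = ctx_test %||% keys(n_te, kind_test, y_test, "TE"),
    space = "latent"
  ), class = "das_embedding_index")
}

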