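test_that("inclusion filters keep exactly the qualifying patients", {
  reg <- filter_patients(toy_registry())
  kept <- sort(unique(reg$demographics$patient_id))
  expect_identical(kept, c("T1", "T5", "T7"))
  # the dateless medication record was removed
  expect_false(anyNA(reg$medications$date))
  # the scoreless clinical measure of T5 was removed
  expect_equal(sum(reg$clinical_measures$patient_id == "T5"), 3L)
  # every remaining CM carries at least one score
  expect_true(all(!is.na(reg$clinical_measures$das28) |
                    !is.na(reg$clinical_measures$asdas)))
})

test_that("filtering is idempotent", {
  once <- filter_patients(toy_registry())
  twice <- filter_patients(once)
  expect_identical(once, twice)
})

test_that("medication coverage rule keeps the smallest covering drug set", {
  reg <- toy_registry()
  # frequencies 70/20/10 -> top two drugs cover 90%
  reg$medications <- tibble::tibble(
    patient_id = "T1",
    date = as.Date("2020-01-01") + 0:99,
    drug = rep(c("a", "b", "c"), c(70, 20, 10)),
    category = "csDMARD", event = "start"
  )
  kept <- select_medications(reg, coverage = 0.90)$medications
  expect_setequal(unique(kept$drug), c("a", "b"))
  all_kept <- select_medications(reg, coverage = 1.0)$medications
  expect_setequal(unique(all_kept$drug), c("a", "b", "c"))
  # a single drug is kept regardless of coverage
  reg$medications <- reg$medications[1:5, ]
  expect_equal(nrow(select_medications(reg, 0.9)$medications), 5L)
  # empty medication table is a no-op
  reg$medications <- reg$medications[0, ]
  expect_equal(nrow(select_medications(reg, 0.9)$medications), 0L)
})

test_that("instances start at the second clinical measure", {
  reg <- filter_patients(toy_registry())
  inst <- build_instances(reg)
  # T1 has 4 CMs -> 3 instances; T5 has 3 scored CMs -> 2; T7 has 3 -> 2
  expect_equal(sum(inst$patient_id == "T1"), 3L)
  expect_equal(sum(inst$patient_id == "T5"), 2L)
  expect_equal(sum(inst$patient_id == "T7"), 2L)
  expect_true(all(inst$target_index >= 2L))
  expect_identical(unique(inst$score_kind[inst$patient_id == "T7"]), "asdas")
})

test_that("the eligibility cutoff is inclusive at exactly lag_days", {
  d <- as.Date("2020-06-01")
  reg <- structure(list(
    demographics = tibble::tibble(patient_id = "X", age = 50, sex = "F",
                                  diagnosis = "RA"),
    clinical_measures = tibble::tibble(
      patient_id = "X",
      date = c(d - 100, d - 15, d),
      das28 = c(4, 3.5, 3), asdas = NA_real_
    ),
    medications = tibble::tibble(
      patient_id = "X", date = d - 14, drug = "methotrexate",
      category = "csDMARD", event = "start"
    ),
    prom = tibble::tibble(patient_id = character(), date = as.Date(character()),
                          radai_score = numeric())
  ), class = "das_registry")
  inst <- build_instances(reg, lag_days = 15L)
  last <- inst[inst$target_index == 3L, ]
  # CM at exactly 15 days before the target is included ...
  expect_equal(last$n_cm, 2L)
  # ... the medication event 14 days before is not
  expect_equal(last$n_med, 0L)
  expect_equal(last$t_days, 15)
})

test_that("no instance sees events closer than the cutoff (no leakage)", {
  reg <- small_cohort(n = 30L, seed = 9L)
  inst <- build_instances(reg, lag_days = 15L)
  for (nm in c("clinical_measures", "medications", "prom")) {
    tbl <- reg[[nm]]
    joined <- dplyr::inner_join(
      inst[c("patient_id", "target_date", "n_cm", "n_med", "n_prom")],
      tbl[c("patient_id", "date")],
      by = "patient_id", relationship = "many-to-many"
    )
    counted <- joined |>
      dplyr::group_by(.data$patient_id, .data$target_date) |>
      dplyr::summarise(
        n_ok = sum(.data$date <= .data$target_date - 15), .groups = "drop"
      )
    col <- c(clinical_measures = "n_cm", medications = "n_med",
             prom = "n_prom")[[nm]]
    check <- dplyr::left_join(
      dplyr::distinct(inst, .data$patient_id, .data$target_date,
                      .data[[col]]),
      counted, by = c("patient_id", "target_date")
    )
    check$n_ok[is.na(check$n_ok)] <- 0L # patients without events of this kind
    expect_equal(check[[col]], check$n_ok)
  }
})

test_that("prior scores become input features for later targets", {
  reg <- filter_patients(toy_registry())
  std <- fit_standardiser(reg)
  enc <- apply_standardiser(std, reg)
  expect_true(all(c("das28", "asdas", "das28_avail") %in%
                    colnames(enc$clinical_measures$X)))
  inst <- build_instances(reg)
  t1 <- inst[inst$patient_id == "T1" & inst$target_index == 3L, ]
  expect_equal(t1$n_cm, 2L) # CMs 1 and 2 (with their DAS) are in the history
})

test_that("stratified split respects fractions, folds and determinism", {
  reg <- small_cohort(n = 100L, seed = 31L)
  sp <- stratified_split(reg, test_fraction = 0.2, n_folds = 5L, seed = 4L)
  expect_setequal(sp$patient_id, reg$demographics$patient_id)
  n_test <- sum(sp$split == "test")
  expect_lt(abs(n_test - 0.2 * nrow(sp)), 0.05 * nrow(sp))
  expect_true(all(is.na(sp$fold[sp$split == "test"])))
  expect_true(all(!is.na(sp$fold[sp$split == "train"])))
  expect_setequal(unique(sp$fold[sp$split == "train"]), 1:5)
  sp2 <- stratified_split(reg, test_fraction = 0.2, n_folds = 5L, seed = 4L)
  expect_identical(sp, sp2)
  # homogeneous stratum: exactly 20 of 100
  regu <- reg
  regu$clinical_measures <- regu$clinical_measures |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(1:5) |>
    dplyr::ungroup()
  keep <- names(which(table(regu$clinical_measures$patient_id) == 5L))
  regu$demographics <- dplyr::filter(regu$demographics,
                                     .data$patient_id %in% keep)
  spu <- stratified_split(regu, seed = 1L)
  expect_equal(sum(spu$split == "test"), round(0.2 * length(keep)))
  expect_error(stratified_split(structure(list(
    clinical_measures = toy_registry()$clinical_measures[0, ]
  ), class = "das_registry")), "Empty cohort")
})

test_that("standardiser reproduces closed-form z-scores and imputes", {
  reg <- toy_registry()
  reg$clinical_measures$crp <- NA_real_
  reg$clinical_measures$crp[reg$clinical_measures$patient_id == "T1"] <-
    c(1, 2, 3, NA)
  std <- fit_standardiser(reg, patient_ids = "T1")
  # population sd of {1,2,3} is sqrt(2/3)
  expect_equal(std$clinical_measures$cont$crp$mean, 2)
  expect_equal(std$clinical_measures$cont$crp$sd, sqrt(2 / 3))
  enc <- apply_standardiser(std, reg)
  x <- enc$clinical_measures$X
  t1 <- x[enc$clinical_measures$patient_id == "T1", "crp"]
  expect_equal(sort(t1[t1 != 0]), c(-1, 1) * 1.5 / sqrt(1.5),
               tolerance = 1e-6)
  expect_equal(unname(t1[4]), 0) # imputed to the training mean
  expect_equal(unname(x[enc$clinical_measures$patient_id == "T1",
                        "crp_avail"]), c(1, 1, 1, 0))
  # z-scores of {1,2,3}: -1.2247, 0, 1.2247 (plus the imputed fourth value)
  expect_equal(unname(sort(t1)), c(-1.224745, 0, 0, 1.224745),
               tolerance = 1e-6)
})

test_that("an all-missing feature is flagged constant and encoded as zero", {
  reg <- toy_registry()
  reg$prom$radai_score <- NA_real_
  std <- fit_standardiser(reg)
  expect_true(std$prom$cont$radai_score$constant)
  enc <- apply_standardiser(std, reg)
  expect_true(all(enc$prom$X[, "radai_score"] == 0))
  expect_true(all(enc$prom$X[, "radai_score_avail"] == 0))
})

test_that("standardising training data reproduces mean zero", {
  reg <- small_cohort(n = 25L, seed = 8L)
  std <- fit_standardiser(reg)
  enc <- apply_standardiser(std, reg)
  X <- enc$clinical_measures$X
  for (cl in c("crp", "bsr")) {
    v <- X[X[, paste0(cl, "_avail")] == 1, cl]
    expect_lt(abs(mean(v)), 1e-9)
    expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-9)
  }
})

test_that("standardiser fitted on train only differs from train+test fit", {
  reg <- small_cohort(n = 40L, seed = 12L)
  sp <- stratified_split(reg, seed = 12L)
  train_ids <- sp$patient_id[sp$split == "train"]
  std_train <- fit_standardiser(reg, train_ids)
  std_all <- fit_standardiser(reg)
  expect_false(isTRUE(all.equal(std_train$clinical_measures$cont$crp$mean,
                                std_all$clinical_measures$cont$crp$mean)))
})

test_that("unparseable and missing-date records are flagged for removal", {
  dir <- withr::local_tempdir()
  reg <- toy_registry()
  write_registry(reg, dir)
  back <- load_registry(dir)
  expect_true(anyNA(back$medications$date)) # the dateless row survives load
  filtered <- filter_patients(back)
  expect_false(anyNA(filtered$medications$date))
  expect_error(load_registry(withr::local_tempdir()), "Missing registry")
})
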