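test_that("knn_query matches exhaustive L1 search on a hand fixture", {
  R_train <- matrix(c(0, 0, 1, 0, 0, 2, 3, 3, -1, 1), 5, 2, byrow = TRUE)
  idx <- manual_index(R_train, matrix(c(0.4, 0.1), 1), y_train = 1:5,
                      y_test = 0)
  got <- knn_query(idx, c(0.4, 0.1), k = 5L)
  oracle <- oracle_knn(R_train, c(0.4, 0.1), 5L)
  expect_identical(got$neighbours, oracle$neighbours)
  expect_equal(got$distances, oracle$distances, tolerance = 1e-10)
  expect_true(all(diff(got$distances) >= 0))
  expect_error(knn_query(idx, c(0, 0), k = 0L), "at least 1")
})

test_that("duplicate embeddings are retrieved first at distance zero", {
  R_train <- matrix(rnorm(20), 10, 2)
  e <- R_train[7, ]
  idx <- manual_index(R_train, matrix(e, 1), y_train = rnorm(10), y_test = 0)
  got <- knn_query(idx, e, k = 3L)
  expect_equal(got$neighbours[1], 7L)
  expect_equal(got$distances[1], 0)
})

test_that("knn regression equals its brute-force oracle on a toy index", {
  set.seed(14)
  R_train <- matrix(rnorm(50 * 3), 50, 3)
  R_test <- matrix(rnorm(6 * 3), 6, 3)
  y_train <- rnorm(50, 3)
  y_test <- rnorm(6, 3)
  idx <- manual_index(R_train, R_test, y_train, y_test)
  res <- knn_regress(idx, k = 5L)
  oracle_pred <- vapply(seq_len(6), function(i) {
    nn <- oracle_knn(R_train, R_test[i, ], 5L)$neighbours
    mean(y_train[nn])
  }, numeric(1))
  expect_equal(res$predictions$y_pred, oracle_pred, tolerance = 1e-10)
  expect_equal(res$mse$mse, mean((oracle_pred - y_test)^2),
               tolerance = 1e-10)
  # neighbours' targets {2, 4} -> prediction 3
  idx2 <- manual_index(matrix(c(0, 0, 0.1, 0, 9, 9), 3, 2, byrow = TRUE),
                       matrix(c(0, 0), 1), y_train = c(2, 4, 100),
                       y_test = 3)
  expect_equal(knn_regress(idx2, k = 2L)$predictions$y_pred, 3)
})

test_that("k = |train| reduces to the per-score train mean", {
  set.seed(15)
  idx <- manual_index(
    matrix(rnorm(40), 20, 2), matrix(rnorm(8), 4, 2),
    y_train = rnorm(20, 4), y_test = rnorm(4, 4),
    kind_train = rep(c("das28", "asdas"), 10),
    kind_test = rep(c("das28", "asdas"), 2)
  )
  res <- knn_regress(idx, k = 20L)
  for (s in c("das28", "asdas")) {
    mu <- mean(idx$train$y_true[idx$train$score_kind == s])
    expect_true(all(abs(
      res$predictions$y_pred[res$predictions$score_kind == s] - mu
    ) < 1e-10))
  }
  # MSE at k = |train| equals the variance of test targets around that mean
  das <- idx$test$score_kind == "das28"
  mu <- mean(idx$train$y_true[idx$train$score_kind == "das28"])
  expect_equal(res$mse$mse[res$mse$score_kind == "das28"],
               mean((idx$test$y_true[das] - mu)^2), tolerance = 1e-10)
})

test_that("neighbours of a different score kind are excluded from the mean", {
  idx <- manual_index(
    matrix(c(0, 0, 0.1, 0.1, 0.2, 0), 3, 2, byrow = TRUE),
    matrix(c(0, 0), 1),
    y_train = c(2, 6, 3), y_test = 4,
    kind_train = c("das28", "asdas", "das28"), kind_test = "das28"
  )
  res <- knn_regress(idx, k = 3L)
  expect_equal(res$predictions$y_pred, mean(c(2, 3)))
  expect_equal(res$predictions$n_used, 2L)
})

test_that("random-subset baseline is reproducible and uses uniform subsets", {
  set.seed(16)
  idx <- manual_index(matrix(rnorm(60), 30, 2), matrix(rnorm(10), 5, 2),
                      y_train = rnorm(30), y_test = rnorm(5))
  r1 <- random_subset_baseline(idx, k = 10L, seed = 2L)
  r2 <- random_subset_baseline(idx, k = 10L, seed = 2L)
  expect_identical(r1$predictions, r2$predictions)
  expect_false(identical(
    r1$predictions$y_pred,
    random_subset_baseline(idx, k = 10L, seed = 3L)$predictions$y_pred
  ))
})

test_that("AAD matches its hand-computed fixtures and scale behaviour", {
  # one test embedding x = 4 with neighbours {3, 5}: AAD 0
  ctx_tr <- tibble::tibble(feat = c(3, 5))
  ctx_te <- tibble::tibble(feat = 4)
  idx <- manual_index(matrix(c(0, 0, 0, 0), 2, 2), matrix(c(0, 0), 1),
                      y_train = 1:2, y_test = 1,
                      ctx_train = ctx_tr, ctx_test = ctx_te)
  expect_equal(aad(idx, "feat", k = 2L)$aad, 0)
  # neighbours {2, 3}: AAD = |4 - 2.5| = 1.5
  idx$context_train <- tibble::tibble(feat = c(2, 3))
  a <- aad(idx, "feat", k = 2L)
  expect_equal(a$aad, 1.5, tolerance = 1e-10)
  # doubling the feature scale doubles AAD but not standardised AAD
  idx2 <- idx
  idx2$context_train$feat <- idx2$context_train$feat * 2
  idx2$context_test$feat <- idx2$context_test$feat * 2
  a2 <- aad(idx2, "feat", k = 2L)
  expect_equal(a2$aad, 2 * a$aad, tolerance = 1e-10)
  expect_equal(a2$aad_std, a$aad_std, tolerance = 1e-10)
})

test_that("AAD equals the exhaustive oracle with partial availability", {
  set.seed(17)
  n_tr <- 50L
  n_te <- 12L
  R_tr <- matrix(rnorm(n_tr * 3), n_tr, 3)
  R_te <- matrix(rnorm(n_te * 3), n_te, 3)
  x_tr <- rnorm(n_tr, 10, 4)
  x_tr[sample(n_tr, 8)] <- NA
  x_te <- rnorm(n_te, 10, 4)
  x_te[sample(n_te, 3)] <- NA
  idx <- manual_index(R_tr, R_te, rnorm(n_tr), rnorm(n_te),
                      ctx_train = tibble::tibble(feat = x_tr),
                      ctx_test = tibble::tibble(feat = x_te))
  nn <- t(vapply(seq_len(n_te),
                 function(i) oracle_knn(R_tr, R_te[i, ], 7L)$neighbours,
                 integer(7)))
  got <- aad(idx, "feat", k = 7L)
  want <- oracle_aad(x_te, x_tr, nn, sd(x_tr[!is.na(x_tr)]))
  expect_equal(got$aad, unname(want["aad"]), tolerance = 1e-10)
  expect_equal(got$aad_std, unname(want["aad_std"]), tolerance = 1e-10)
})

test_that("category importance reproduces the worked adjusted probability", {
  # 2 test embeddings of category A with neighbour categories {A,A,B} and
  # {A,B,B}: adjusted = (2 + 1) / (3 + 3) = 0.5
  R_tr <- matrix(c(0, 0, 0, 1, 1, 0, 10, 10, 10, 11, 11, 10), 6, 2,
                 byrow = TRUE)
  R_te <- matrix(c(0.1, 0.1, 10.1, 10.1), 2, 2, byrow = TRUE)
  ctx_tr <- tibble::tibble(grp = c("A", "A", "B", "A", "B", "B"))
  ctx_te <- tibble::tibble(grp = c("A", "A"))
  idx <- manual_index(R_tr, R_te, rnorm(6), rnorm(2),
                      ctx_train = ctx_tr, ctx_test = ctx_te)
  ci <- category_importance(idx, "grp", k = 3L)
  a_row <- ci[ci$category == "A", ]
  expect_equal(a_row$adjusted, 0.5, tolerance = 1e-10)
  expect_equal(a_row$prior, 0.5, tolerance = 1e-10)
  expect_equal(a_row$increase_pct, 0)
  # priors sum to one over categories
  expect_equal(sum(ci$prior), 1, tolerance = 1e-10)
  # oracle agreement
  nn <- t(vapply(1:2, function(i) oracle_knn(R_tr, R_te[i, ], 3L)$neighbours,
                 integer(3)))
  expect_equal(a_row$adjusted, oracle_adjusted(ctx_te$grp, ctx_tr$grp, nn, "A"),
               tolerance = 1e-10)
  # a category absent from the test indices gets NA adjusted probability
  expect_true(is.na(ci$adjusted[ci$category == "B"]))
})

test_that("random neighbourhoods give adjusted probabilities near the prior", {
  set.seed(18)
  n_tr <- 400L
  n_te <- 200L
  grp_tr <- sample(c("A", "B"), n_tr, replace = TRUE, prob = c(0.7, 0.3))
  grp_te <- sample(c("A", "B"), n_te, replace = TRUE, prob = c(0.7, 0.3))
  # embeddings carry no information about the category
  idx <- manual_index(matrix(rnorm(n_tr * 2), n_tr, 2),
                      matrix(rnorm(n_te * 2), n_te, 2),
                      rnorm(n_tr), rnorm(n_te),
                      ctx_train = tibble::tibble(grp = grp_tr),
                      ctx_test = tibble::tibble(grp = grp_te))
  ci <- category_importance(idx, "grp", k = 50L)
  expect_lt(max(abs(ci$adjusted - ci$prior)), 0.05)
})

test_that("attention summaries average to one per stratum and flag improvement", {
  cf <- cached_small_fit()
  test_ids <- cf$sp$patient_id[cf$sp$split == "test"]
  summ <- summarise_attention(cf$fit, cf$reg, test_ids)
  sums <- summ$global_by_targets |>
    dplyr::group_by(.data$score_kind, .data$n_targets) |>
    dplyr::summarise(s = sum(.data$mean_weight), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-4))
  if (nrow(summ$global_by_improvement) > 0) {
    sums2 <- summ$global_by_improvement |>
      dplyr::group_by(.data$score_kind, .data$improved) |>
      dplyr::summarise(s = sum(.data$mean_weight), .groups = "drop")
    expect_true(all(abs(sums2$s - 1) < 1e-4))
  }
  expect_true(all(summ$local_by_position$reverse_position >= 1))
})

test_that("the improvement flag uses a 20% drop from the prior score", {
  d <- as.Date("2022-01-01")
  reg <- structure(list(
    demographics = tibble::tibble(patient_id = "I1", age = 50, sex = "F",
                                  diagnosis = "RA"),
    clinical_measures = tibble::tibble(
      patient_id = "I1", date = d + c(0, 100, 200),
      das28 = c(4.0, 3.0, 2.9), asdas = NA_real_
    ),
    medications = tibble::tibble(patient_id = "I1", date = d,
                                 drug = "methotrexate", category = "csDMARD",
                                 event = "start"),
    prom = tibble::tibble(patient_id = character(),
                          date = as.Date(character()))
  ), class = "das_registry")
  inst <- build_instances(reg)
  prev <- dasnet:::last_prior_score(reg, inst)
  improved <- (prev - inst$y) / prev >= 0.2
  # prior 4.0 -> current 3.0 is a 25% improvement; 3.0 -> 2.9 is not
  expect_true(improved[inst$target_index == 2L])
  expect_false(improved[inst$target_index == 3L])
})
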