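test_that("persample folds partition the data, one sample per participant", {
  tbl <- subset_endpoints(simulate_cohort(cohort_config())$table,
                          days = 1:2, regions = "ear")
  y <- tbl$participant
  folds <- persample_folds(y, seed = 3, iteration = 7)
  expect_equal(sort(unique(folds)), 1:6)
  for (j in 1:6) {
    test <- y[folds == j]
    expect_equal(sort(test), sort(unique(y)))  # exactly one per participant
  }
  # every sample tested exactly once per iteration
  expect_equal(length(folds), 72)
  expect_identical(persample_folds(y, seed = 3, iteration = 7), folds)
  expect_false(identical(persample_folds(y, seed = 3, iteration = 8),
                         folds))
  expect_error(persample_folds(c("a", "a", "b")), "unequal")
})

test_that("LOO is deterministic, order-invariant, and honours exact copies", {
  sim <- simulate_cohort(cohort_config(seed = 8))
  tbl <- subset_endpoints(drift_correct(sim$table), days = 1,
                          regions = "ear")

  a1 <- run_loo(tbl, knn_config())
  a2 <- run_loo(tbl[sample(nrow(tbl)), ], knn_config())
  expect_equal(a1$mean, a2$mean)
  expect_length(a1$accuracies, 1)

  # make one participant's replicates exact copies: with k = 1 its
  # held-out samples always find an identical twin
  fm <- feature_matrix(tbl)
  idx <- which(tbl$participant == "P05")
  for (i in idx) tbl[i, feature_names(tbl)] <- as.list(fm[idx[1], ])
  res <- run_loo(tbl, knn_config(k = 1))
  # P05's three samples must all be correct, so accuracy >= 3/36 and the
  # copies cannot be what limits accuracy
  d2 <- enoseid:::cross_dist2(feature_matrix(tbl), feature_matrix(tbl))
  preds <- vapply(idx, function(i)
    enoseid:::knn_vote(d2[i, ], factor(tbl$participant), 1, exclude = i),
    character(1))
  expect_true(all(preds == "P05"))
})

test_that("repeated persample CV is seed-deterministic with exact summaries", {
  tbl <- subset_endpoints(drift_correct(
    simulate_cohort(strong_config(regions = "ear"))$table),
    days = 1, regions = "ear")
  r1 <- run_one_per_participant(tbl, knn_config(), n_iterations = 25,
                                seed = 5)
  r2 <- run_one_per_participant(tbl, knn_config(), n_iterations = 25,
                                seed = 5)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_equal(r1$mean, mean(r1$accuracies))
  expect_equal(r1$median, stats::median(r1$accuracies))
  expect_length(r1$accuracies, 25)

  # perfectly separable data: every iteration at 1, sd exactly 0
  expect_equal(r1$accuracies, rep(1, 25))
  expect_equal(r1$sd, 0)
})

test_that("a single accumulated day set reduces to the persample scheme", {
  tbl <- subset_endpoints(simulate_cohort(cohort_config(seed = 4))$table,
                          regions = "ear")
  acc <- run_accumulated_days(tbl, knn_config(), day_sets = list(1),
                              n_iterations = 8, seed = 7)[[1]]
  direct <- run_one_per_participant(
    subset_endpoints(tbl, days = 1), knn_config(), n_iterations = 8,
    seed = enoseid:::hash_seed(7, "days/1"))
  expect_equal(acc$accuracies, direct$accuracies)
})

test_that("accumulated-day folds scale with the data", {
  tbl <- subset_endpoints(simulate_cohort(cohort_config(seed = 4))$table,
                          regions = "ear")
  for (nd in c(2, 4)) {
    sub <- subset_endpoints(tbl, days = seq_len(nd))
    folds <- persample_folds(sub$participant, seed = 1, iteration = 1)
    m <- max(folds)
    expect_equal(m, 3 * nd)
    # each fold trains on m - 1 and tests on 1 sample per participant
    expect_equal(sum(folds == 1 & sub$participant == "P01"), 1)
    expect_equal(sum(folds != 1 & sub$participant == "P01"), m - 1)
  }
})

test_that("across-day holdout refuses overlap and recovers clean cohorts", {
  cfg <- noiseless_config(drift_scale = 0.5)
  tbl <- subset_endpoints(drift_correct(simulate_cohort(cfg)$table),
                          regions = "ear")
  expect_error(run_day_holdout(tbl, knn_config(), train_days = 1:5,
                               test_day = 5), "must not")
  res <- run_day_holdout(tbl, knn_config(), train_days = 1:4, test_day = 5)
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_test, 36)
  expect_error(run_day_holdout(tbl, knn_config(), train_days = 1:4,
                               test_day = 9), "not present")
})

test_that("validation rejects tables that still contain control rows", {
  tbl <- simulate_cohort(cohort_config(n_participants = 3,
                                       n_days = 1))$table
  expect_error(run_loo(tbl), "body-sample")
})
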