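test_that("a body sample equal to its control divides to all ones", {
  tbl <- tiny_table()
  fm <- feature_matrix(tbl)
  tbl[1, feature_names(tbl)] <- as.list(fm[5, ])  # body row 1 == its control
  out <- drift_correct(tbl)
  expect_equal(as.numeric(feature_matrix(out)[1, ]), rep(1, 4))
})

test_that("an all-ones control leaves body endpoints unchanged", {
  tbl <- tiny_table()  # its controls are all ones
  out <- drift_correct(tbl)
  body <- tbl[tbl$kind == "body", ]
  expect_equal(feature_matrix(out), feature_matrix(body))
  expect_equal(attr(out, "drift_correction"), "fresh_control_division")
})

test_that("mode none passes body rows through and drops controls", {
  tbl <- tiny_table()
  out <- drift_correct(tbl, mode = "none")
  expect_true(all(out$kind == "body"))
  expect_equal(feature_matrix(out),
               feature_matrix(tbl[tbl$kind == "body", ]))
})

test_that("correction is equivariant to shared per-sensor day gains", {
  sim <- simulate_cohort(cohort_config(n_participants = 3, n_days = 2,
                                       seed = 31))
  tbl <- sim$table
  base <- drift_correct(tbl)
  feats <- feature_names(tbl)
  scaled <- tibble::as_tibble(tbl)
  for (p in unique(tbl$participant)) for (d in unique(tbl$day)) {
    gains <- exp(stats::rnorm(length(feats), sd = 0.5))
    rows <- scaled$participant == p & scaled$day == d
    scaled[rows, feats] <- sweep(as.matrix(scaled[rows, feats]), 2, gains,
                                 "*")
  }
  rescued <- drift_correct(endpoint_table(scaled))
  expect_equal(feature_matrix(rescued), feature_matrix(base),
               tolerance = 1e-12)
})

test_that("exact drift coupling: corrected endpoints are day-invariant", {
  cfg <- noiseless_config(n_participants = 3, n_days = 4,
                          drift_scale = 0.5)
  out <- drift_correct(simulate_cohort(cfg)$table)
  for (p in unique(out$participant)) for (r in unique(out$region)) {
    fm <- feature_matrix(out[out$participant == p & out$region == r, ])
    expect_true(all(abs(sweep(fm, 2, fm[1, ])) < 1e-12))
  }
})

test_that("control bookkeeping errors are specific", {
  tbl <- tiny_table()
  expect_error(drift_correct(tbl[tbl$kind == "body" |
                                   tbl$participant == "P01", ]),
               "missing fresh control for participant-day P02 1")
  # a duplicated control cannot pass endpoint_table validation, so forge
  # one to exercise drift_correct's own guard
  dup <- rbind(tibble::as_tibble(tbl), tibble::as_tibble(tbl)[5, ])
  class(dup) <- class(tbl)
  expect_error(drift_correct(dup), "duplicate fresh control")
})

test_that("subsetting enforces the sampling arithmetic", {
  tbl <- simulate_cohort(cohort_config())$table
  expect_equal(nrow(subset_endpoints(tbl, days = 1, regions = "ear")), 36)
  expect_equal(nrow(subset_endpoints(tbl, regions = "ear")), 180)
  expect_equal(as.data.frame(subset_endpoints(
    tbl, days = 1:5, kinds = c("body", "fresh_control"))),
    as.data.frame(tbl))
  # a region filter selects body rows only (controls carry no region)
  expect_equal(nrow(subset_endpoints(
    tbl, regions = c("ear", "armpit", "back"))), 540)
  expect_error(subset_endpoints(tbl, days = 7), "not present")
  expect_error(subset_endpoints(tbl, regions = "scalp"), "not present")
  expect_error(subset_endpoints(tbl, days = 1, kinds = "baseline"),
               "not present")
})
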