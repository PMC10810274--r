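test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_config(n_participants = 4, n_days = 2, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$drift, s2$truth$drift)
  s3 <- simulate_cohort(cohort_config(n_participants = 4, n_days = 2,
                                      seed = 43))
  expect_false(identical(s1$table, s3$table))
})

test_that("cohort has the declared sampling structure", {
  sim <- simulate_cohort(cohort_config())
  tbl <- sim$table
  expect_equal(nrow(tbl), 12 * 5 * (3 * 3 + 1))
  expect_equal(sum(tbl$kind == "fresh_control"), 12 * 5)
  per_pd <- dplyr::count(tbl[tbl$kind == "body", ],
                         participant, day, region)
  expect_true(all(per_pd$n == 3))
  expect_true(all(feature_matrix(tbl) > 0))
  expect_length(feature_names(tbl), 20)
})

test_that("noiseless limit: body samples identical across days and replicates", {
  cfg <- noiseless_config(n_participants = 3, n_days = 3)
  tbl <- simulate_cohort(cfg)$table
  body <- tbl[tbl$kind == "body", ]
  for (p in unique(body$participant)) for (r in unique(body$region)) {
    fm <- feature_matrix(body[body$participant == p & body$region == r, ])
    expect_equal(nrow(fm), 9)
    expect_true(all(abs(sweep(fm, 2, fm[1, ])) < 1e-12))
  }
})

test_that("ground truth reconstructs expected noiseless endpoints", {
  # kappa = 1: no idiosyncratic body-drift term, so with zero replicate
  # noise the realized endpoints equal their expectation exactly
  cfg <- cohort_config(n_participants = 3, n_days = 2,
                       replicate_noise_scale = 0, drift_coupling = 1,
                       seed = 9)
  sim <- simulate_cohort(cfg)
  tbl <- sim$table
  i <- which(tbl$participant == "P02" & tbl$day == 2 &
               tbl$kind == "body" & tbl$region == "armpit" &
               tbl$replicate == 1)
  expect_equal(as.numeric(feature_matrix(tbl)[i, ]),
               true_endpoints(sim$truth, "P02", 2, "armpit"),
               tolerance = 1e-12)
  j <- which(tbl$participant == "P03" & tbl$day == 1 &
               tbl$kind == "fresh_control")
  expect_equal(as.numeric(feature_matrix(tbl)[j, ]),
               true_endpoints(sim$truth, "P03", 1),
               tolerance = 1e-12)
})

test_that("subsetting the design reproduces the shared records", {
  big <- simulate_cohort(cohort_config(seed = 5))$table
  small <- simulate_cohort(cohort_config(n_days = 2, seed = 5))$table
  big12 <- subset_endpoints(big, days = 1:2)
  expect_equal(as.data.frame(big12), as.data.frame(small))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(baseline_level = -1), "positive")
  expect_error(cohort_config(baseline_level = 0), "positive")
  expect_error(cohort_config(drift_coupling = -0.5), "drift_coupling")
  expect_error(cohort_config(n_participants = 1), ">= 2")
  expect_error(cohort_config(signature_scale = -0.1), ">= 0")
  expect_error(cohort_config(n_days = 0), "positive integers")
})

test_that("time series follow the saturating-exponential curve family", {
  cfg <- noiseless_config(n_participants = 2, n_days = 1,
                          regions = "ear")
  recs <- simulate_time_series(cfg, duration_s = 50, rate_hz = 1,
                               tau_s = 5)
  expect_length(recs, (2 * 3 + 2) * 2)  # (3 reps + control) x 2 devices

  sim <- simulate_cohort(cfg)
  r1 <- recs[[1]]
  fm <- feature_matrix(sim$table)
  E <- unname(fm[1, seq_len(10)])
  # closed form: G(50) differs from E by (E-1) exp(-50/tau)
  expect_equal(r1$channels[, 50], E - (E - 1) * exp(-50 / 5),
               tolerance = 1e-12)
  # monotone approach, starting near 1
  expect_true(all(abs(r1$channels[, 1] - 1) < abs(E - 1) + 1e-12))

  # tau -> 0 limit: step to E at the first sample
  step <- simulate_time_series(cfg, duration_s = 10, tau_s = 1e-9)[[1]]
  expect_equal(step$channels[, 1], E, tolerance = 1e-9)

  expect_error(simulate_time_series(cfg, tau_s = 0), "positive")
  expect_error(simulate_time_series(cfg, duration_s = 0), "duration")
})

test_that("flat unit series when all endpoints are 1", {
  cfg <- cohort_config(n_participants = 2, n_days = 1, regions = "ear",
                       signature_scale = 0, signature_day_jitter = 0,
                       drift_scale = 0, replicate_noise_scale = 0,
                       device_gain_scale = 0, baseline_level = 1)
  recs <- simulate_time_series(cfg, duration_s = 20)
  for (r in recs) expect_true(all(r$channels == 1))
})
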