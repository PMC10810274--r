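# Shared cohort configurations for tests.

# strongly identifiable cohort with exactly coupled drift: fresh-control
# division removes drift exactly, signatures dominate noise
strong_config <- function(regions = c("ear", "armpit", "back"), seed = 1,
                          ...) {
  cohort_config(regions = regions,
                signature_scale = 0.6,
                signature_day_jitter = 0.02,
                drift_coupling = 1,
                replicate_noise_scale = 0.05,
                seed = seed, ...)
}

# no participant signal at all: identification must be at chance
null_config <- function(regions = "ear", seed = 1, ...) {
  cohort_config(regions = regions,
                signature_scale = 0,
                signature_day_jitter = 0,
                seed = seed, ...)
}

# fully deterministic cohort: no noise, no jitter; drift optional (and
# exactly coupled, so control division removes it when present)
noiseless_config <- function(..., drift_scale = 0, seed = 1) {
  cohort_config(signature_scale = 0.4,
                signature_day_jitter = 0,
                drift_scale = drift_scale,
                drift_coupling = 1,
                replicate_noise_scale = 0,
                device_gain_scale = 0,
                seed = seed, ...)
}

# small tidy endpoint table built by hand
tiny_table <- function() {
  endpoint_table(tibble::tibble(
    participant = c("P01", "P01", "P02", "P02", "P01", "P02"),
    day = 1L,
    kind = c("body", "body", "body", "body",
             "fresh_control", "fresh_control"),
    region = c("ear", "ear", "ear", "ear", NA, NA),
    replicate = c(1L, 2L, 1L, 2L, NA, NA),
    d1_s1 = c(1.0, 1.1, 2.0, 2.1, 1.0, 1.0),
    d1_s2 = c(0.5, 0.55, 0.9, 0.95, 1.0, 1.0),
    d2_s1 = c(1.4, 1.5, 2.4, 2.5, 1.0, 1.0),
    d2_s2 = c(0.7, 0.75, 1.1, 1.15, 1.0, 1.0)))
}
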