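#' Simulate a body-odor eNose cohort with known ground truth
#'
#' Generates an [endpoint_table] with the structure of a multi-day
#' identification study: every participant-day contributes
#' `replicates_per_region_day` body samples per region plus exactly one
#' matched fresh-control sample, each measured by all devices and fused
#' into one feature vector. All multiplicative model terms (signatures,
#' day jitter, drift, noise) are returned as ground truth so tests can
#' reconstruct the expected noiseless endpoints.
#'
#' Randomness is drawn from deterministic per-entity streams derived from
#' `config$seed`: re-simulating with fewer days or participants reproduces
#' exactly the records the designs share.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_sim` with elements `table` (the
#'   [endpoint_table]) and `truth`, a list holding `baseline` (sensor
#'   baselines), `device_gain` (device x sensor), `drift`
#'   (day x device x sensor; body samples carry `drift^kappa`),
#'   `signature` (participant x region x sensor), `day_jitter`
#'   (participant x region x day x sensor) and the `config` echo.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 3, n_days = 2))
#' dim(sim$table)
#' table(sim$table$kind)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  seed <- cfg$seed
  P <- cfg$n_participants; D <- cfg$n_days; V <- cfg$n_devices
  S <- cfg$sensors_per_device; R <- length(cfg$regions)
  reps <- cfg$replicates_per_region_day
  participants <- sprintf("P%02d", seq_len(P))
  kappa <- cfg$drift_coupling
  idio_scale <- (1 - min(kappa, 1)) * cfg$drift_scale

  # fixed per-device sensor gains; device 1 is the reference
  gain <- matrix(1, V, S)
  if (V > 1) for (v in 2:V)
    gain[v, ] <- exp(stream_rnorm(S, seed, paste0("gain/", v),
                                  cfg$device_gain_scale))

  drift <- array(NA_real_, c(D, V, S))
  for (d in seq_len(D)) for (v in seq_len(V))
    drift[d, v, ] <- exp(stream_rnorm(S, seed, paste0("drift/", d, "/", v),
                                      cfg$drift_scale))

  signature <- array(NA_real_, c(P, R, S),
                     dimnames = list(participants, cfg$regions, NULL))
  day_jitter <- array(NA_real_, c(P, R, D, S),
                      dimnames = list(participants, cfg$regions, NULL, NULL))
  for (p in seq_len(P)) {
    for (r in seq_len(R)) {
      reg <- cfg$regions[r]
      signature[p, r, ] <- exp(stream_rnorm(
        S, seed, paste0("sig/", participants[p], "/", reg),
        cfg$signature_scale[[reg]]))
      for (d in seq_len(D))
        day_jitter[p, r, d, ] <- exp(stream_rnorm(
          S, seed, paste0("jit/", participants[p], "/", reg, "/", d),
          cfg$signature_day_jitter[[reg]]))
    }
  }

  feat_cols <- as.vector(vapply(seq_len(V), function(v)
    paste0("d", v, "_s", seq_len(S)), character(S)))

  fused_row <- function(per_device) as.vector(t(per_device))

  rows <- vector("list", P * D * (R * reps + 1 +
                                    cfg$include_overnight_control))
  meta <- vector("list", length(rows))
  i <- 0L
  for (p in seq_len(P)) {
    pid <- participants[p]
    for (d in seq_len(D)) {
      controls <- "fresh_control"
      if (cfg$include_overnight_control)
        controls <- c("overnight_control", controls)
      for (kind in controls) {
        per_dev <- matrix(NA_real_, V, S)
        for (v in seq_len(V)) {
          noise <- stream_rnorm(S, seed,
                                paste0("noise/", pid, "/", d, "/", kind,
                                       "/", v),
                                cfg$replicate_noise_scale)
          per_dev[v, ] <- cfg$baseline_level * gain[v, ] * drift[d, v, ] *
            exp(noise)
        }
        i <- i + 1L
        rows[[i]] <- fused_row(per_dev)
        meta[[i]] <- list(pid, d, kind, NA_character_, NA_integer_)
      }
      for (r in seq_len(R)) {
        reg <- cfg$regions[r]
        for (rep_i in seq_len(reps)) {
          per_dev <- matrix(NA_real_, V, S)
          for (v in seq_len(V)) {
            noise <- stream_rnorm(S, seed,
                                  paste0("noise/", pid, "/", d, "/", reg,
                                         "/", rep_i, "/", v),
                                  cfg$replicate_noise_scale)
            # the sample's own departure from the control's drift; scale
            # vanishes at exact coupling (kappa = 1)
            idio <- stream_rnorm(S, seed,
                                 paste0("idio/", pid, "/", d, "/", reg,
                                        "/", rep_i, "/", v),
                                 idio_scale)
            per_dev[v, ] <- cfg$baseline_level * gain[v, ] *
              drift[d, v, ]^kappa * exp(idio) * signature[p, r, ] *
              day_jitter[p, r, d, ] * exp(noise)
          }
          i <- i + 1L
          rows[[i]] <- fused_row(per_dev)
          meta[[i]] <- list(pid, d, "body", reg, rep_i)
        }
      }
    }
  }

  fm <- do.call(rbind, rows[seq_len(i)])
  colnames(fm) <- feat_cols
  md <- do.call(rbind, lapply(meta[seq_len(i)], function(m)
    tibble::tibble(participant = m[[1]], day = as.integer(m[[2]]),
                   kind = m[[3]], region = m[[4]],
                   replicate = as.integer(m[[5]]))))
  tbl <- endpoint_table(dplyr::bind_cols(md, tibble::as_tibble(fm)))

  truth <- list(baseline = cfg$baseline_level, device_gain = gain,
                drift = drift, signature = signature,
                day_jitter = day_jitter, config = cfg)
  structure(list(table = tbl, truth = truth), class = "cohort_sim")
}

#' Expected noiseless endpoints for a simulated body sample
#'
#' Reconstructs, from a `cohort_sim`'s ground truth, the fused feature
#' vector a body (or fresh-control) sample would have with zero replicate
#' noise. Used to verify that the generator and the analysis agree.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param participant Participant label, e.g. `"P01"`.
#' @param day Day index.
#' @param region Region label for body samples, or `NULL` for the
#'   fresh-control sample.
#' @return Numeric vector ordered like the table's feature columns.
#' @export
true_endpoints <- function(truth, participant, day, region = NULL) {
  cfg <- truth$config
  p <- match(participant, sprintf("P%02d", seq_len(cfg$n_participants)))
  V <- cfg$n_devices; S <- cfg$sensors_per_device
  out <- matrix(NA_real_, V, S)
  for (v in seq_len(V)) {
    if (is.null(region)) {
      out[v, ] <- truth$baseline * truth$device_gain[v, ] *
        truth$drift[day, v, ]
    } else {
      r <- match(region, cfg$regions)
      out[v, ] <- truth$baseline * truth$device_gain[v, ] *
        truth$drift[day, v, ]^cfg$drift_coupling *
        truth$signature[p, r, ] * truth$day_jitter[p, r, day, ]
    }
  }
  as.vector(t(out))
}

#' Simulate raw eNose measurement-phase time series
#'
#' Generates, for every measurement of the cohort design, the 10-channel
#' conductivity time course of the measurement phase. Each channel rises
#' (or falls) exponentially from the clean-baseline level 1 toward its
#' endpoint `E`:
#' \deqn{G(t) = 1 + (E - 1)(1 - e^{-t/\tau})}
#' so the last sample equals `E` up to `(E-1) exp(-duration/tau)`.
#' Endpoints are the same values [simulate_cohort()] would produce for the
#' identical configuration and seed, so extracting endpoints from these
#' series and fusing devices reproduces the cohort's endpoint table.
#'
#' @param config A [cohort_config()].
#' @param duration_s Length of the measurement phase in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param tau_s Sensor time constant(s) in seconds; scalar or one per
#'   sensor; strictly positive.
#' @return A list of `measurement_record` objects, each with metadata
#'   fields (`participant`, `day`, `kind`, `region`, `replicate`,
#'   `device`), a `time` vector and a `channels` matrix (sensors x time).
#' @export
simulate_time_series <- function(config, duration_s = 50, rate_hz = 1,
                                 tau_s = 8) {
  stopifnot(inherits(config, "cohort_config"))
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  S <- config$sensors_per_device
  if (length(tau_s) == 1) tau_s <- rep(tau_s, S)
  if (length(tau_s) != S)
    stop("tau_s must be scalar or one value per sensor", call. = FALSE)
  if (any(tau_s <= 0)) stop("tau_s must be strictly positive", call. = FALSE)

  sim <- simulate_cohort(config)
  tbl <- sim$table
  V <- config$n_devices
  tgrid <- seq(1 / rate_hz, duration_s, by = 1 / rate_hz)

  records <- vector("list", nrow(tbl) * V)
  k <- 0L
  fm <- feature_matrix(tbl)
  for (i in seq_len(nrow(tbl))) {
    for (v in seq_len(V)) {
      E <- fm[i, (v - 1) * S + seq_len(S)]
      channels <- matrix(NA_real_, S, length(tgrid))
      for (s in seq_len(S))
        channels[s, ] <- 1 + (E[s] - 1) * (1 - exp(-tgrid / tau_s[s]))
      k <- k + 1L
      records[[k]] <- structure(list(
        participant = tbl$participant[i], day = tbl$day[i],
        kind = tbl$kind[i], region = tbl$region[i],
        replicate = tbl$replicate[i], device = v,
        time = tgrid, channels = channels),
        class = "measurement_record")
    }
  }
  records
}
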