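#' Configuration of a simulated eNose sampling cohort
#'
#' Describes the sampling design and the generative model of a synthetic
#' body-odor cohort: how many participants visit the lab on how many
#' consecutive days, which body regions are sampled how many times per day,
#' how many eNose devices (each a 10-sensor metal-oxide array) record every
#' measurement, and the log-normal scales of the multiplicative terms that
#' make up each sensor endpoint.
#'
#' The endpoint of sensor `s` on device `v` for a body sample of participant
#' `p`, region `r`, day `d` is modelled as
#'
#' \deqn{E = B_s \, g_{vs} \, D_{dvs}^{\kappa} \, e^{\eta} \,
#'       S_{prs} \, J_{prds} \, e^{\epsilon}}
#'
#' where `B` is the per-sensor baseline conductivity ratio, `g` a fixed
#' per-device sensor gain, `D` the day-by-device drift factor, `S` the
#' participant's region-specific signature, `J` its day-to-day jitter and
#' `eps` replicate noise; all stochastic terms are log-normal. The matched
#' fresh-control sample of the same participant-day carries the full drift
#' factor `D` (exponent 1) and no signature, so dividing body endpoints by
#' control endpoints removes drift exactly when the coupling exponent
#' `drift_coupling` is 1. For `drift_coupling < 1` the body samples drift
#' partly idiosyncratically (the term `eta`, of scale
#' `(1 - min(kappa, 1)) * drift_scale`), so control division is only an
#' approximate correction — emulating the empirical finding that reference
#' division helps within-day but can hurt across days. The idiosyncratic
#' term `eta` is drawn independently per measurement, so it carries no
#' participant information: with `signature_scale = 0` every validation
#' design sits at chance.
#'
#' @param n_participants Number of participants (classes). Default 12.
#' @param n_days Number of consecutive sampling days. Default 5.
#' @param regions Character vector of body-region labels.
#' @param replicates_per_region_day Samples per region per participant-day.
#' @param n_devices Number of eNose devices measuring each sample.
#' @param sensors_per_device Sensors per device.
#' @param signature_scale Log-scale of participant-specific multiplicative
#'   sensor signatures; scalar or named per region.
#' @param signature_day_jitter Log-scale of day-to-day signature wobble;
#'   scalar or named per region. Smaller means a more stable odor source.
#' @param drift_scale Log-scale of the multiplicative day-by-device drift.
#' @param drift_coupling Exponent `kappa >= 0` governing how faithfully body
#'   samples follow the control sample's drift (1 = exactly).
#' @param replicate_noise_scale Log-scale of per-measurement noise.
#' @param device_gain_scale Log-scale of fixed per-device sensor gains
#'   (device 1 is the gain reference).
#' @param baseline_level Per-sensor nominal endpoint (conductivity ratio
#'   G0/G, unitless); scalar or length `sensors_per_device`, strictly
#'   positive. The default profile includes one sensor below 1, mimicking a
#'   sensor that responds with a negative signal.
#' @param include_overnight_control If `TRUE`, also emit one overnight
#'   control record per participant-day; these are pass-through records the
#'   analysis ignores.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()], [read_cohort_config()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 4, n_days = 2)
#' cfg$regions
cohort_config <- function(n_participants = 12,
                          n_days = 5,
                          regions = c("ear", "armpit", "back"),
                          replicates_per_region_day = 3,
                          n_devices = 2,
                          sensors_per_device = 10,
                          signature_scale = 0.20,
                          signature_day_jitter = 0.10,
                          drift_scale = 0.25,
                          drift_coupling = 0.7,
                          replicate_noise_scale = 0.10,
                          device_gain_scale = 0.05,
                          baseline_level = c(1.10, 0.60, 1.05, 1.35, 1.10,
                                             1.80, 2.40, 1.60, 1.90, 1.25),
                          include_overnight_control = FALSE,
                          seed = 1L) {
  counts <- c(n_participants = n_participants, n_days = n_days,
              replicates_per_region_day = replicates_per_region_day,
              n_devices = n_devices, sensors_per_device = sensors_per_device)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all design counts must be positive integers", call. = FALSE)
  if (n_participants < 2)
    stop("n_participants must be >= 2 for any classification task",
         call. = FALSE)
  regions <- tolower(as.character(regions))
  if (anyDuplicated(regions) || length(regions) < 1)
    stop("regions must be distinct non-empty labels", call. = FALSE)

  expand_region <- function(x, what) {
    if (any(x < 0)) stop(what, " must be >= 0", call. = FALSE)
    if (length(x) == 1) x <- stats::setNames(rep(x, length(regions)), regions)
    if (is.null(names(x)) && length(x) == length(regions))
      names(x) <- regions
    if (!all(regions %in% names(x)))
      stop(what, " must be a scalar or named per region", call. = FALSE)
    x[regions]
  }
  signature_scale <- expand_region(signature_scale, "signature_scale")
  signature_day_jitter <- expand_region(signature_day_jitter,
                                        "signature_day_jitter")

  for (sc in c(drift_scale, replicate_noise_scale, device_gain_scale))
    if (length(sc) != 1 || sc < 0)
      stop("noise/drift scales must be scalar and >= 0", call. = FALSE)
  if (length(drift_coupling) != 1 || drift_coupling < 0)
    stop("drift_coupling must be a scalar >= 0", call. = FALSE)

  if (length(baseline_level) == 1)
    baseline_level <- rep(baseline_level, sensors_per_device)
  if (length(baseline_level) != sensors_per_device)
    stop("baseline_level must be scalar or one value per sensor",
         call. = FALSE)
  if (any(!is.finite(baseline_level)) || any(baseline_level <= 0))
    stop("baseline_level must be strictly positive", call. = FALSE)

  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    regions = regions,
    replicates_per_region_day = as.integer(replicates_per_region_day),
    n_devices = as.integer(n_devices),
    sensors_per_device = as.integer(sensors_per_device),
    signature_scale = signature_scale,
    signature_day_jitter = signature_day_jitter,
    drift_scale = drift_scale,
    drift_coupling = drift_coupling,
    replicate_noise_scale = replicate_noise_scale,
    device_gain_scale = device_gain_scale,
    baseline_level = baseline_level,
    include_overnight_control = isTRUE(include_overnight_control),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [cohort_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(cohort_config, vals)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_participants, " participants x ", x$n_days,
      " days x {", paste(x$regions, collapse = ", "), "} x ",
      x$replicates_per_region_day, " replicates; ",
      x$n_devices, " devices x ", x$sensors_per_device, " sensors\n",
      sep = "")
  cat("  signature scales: ",
      paste(sprintf("%s=%.3g", names(x$signature_scale), x$signature_scale),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  drift %.3g (coupling %.3g), jitter %s, noise %.3g, seed %d\n",
              x$drift_scale, x$drift_coupling,
              paste(sprintf("%.3g", x$signature_day_jitter), collapse = "/"),
              x$replicate_noise_scale, x$seed))
  invisible(x)
}
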