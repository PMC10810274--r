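#' Drift-correct body samples by fresh-control division
#'
#' Sensor endpoints drift from day to day, both because the sensors age
#' and because body odor itself changes. The correction implemented here
#' divides every body sample's fused feature vector, coordinate by
#' coordinate, by the fused feature vector of the matched fresh-control
#' sample — the reference odorant prepared fresh and measured on the same
#' day for the same participant. Division is device-aligned: each device's
#' body endpoints are divided by that same device's control endpoints.
#' Whatever per-sensor multiplicative factor a day imposed on both the
#' body and the control measurement cancels exactly.
#'
#' @param x An [endpoint_table] containing body rows and (for
#'   `mode = "fresh_control_division"`) exactly one `fresh_control` row per
#'   participant-day that has body rows.
#' @param mode `"fresh_control_division"` (the default) or `"none"`, which
#'   passes body rows through unchanged. In both modes only body rows are
#'   returned; control and other auxiliary rows are dropped.
#' @return An [endpoint_table] of body rows with a `drift_correction`
#'   attribute recording the mode.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 3, n_days = 2))
#' corrected <- drift_correct(sim$table)
#' attr(corrected, "drift_correction")
drift_correct <- function(x, mode = c("fresh_control_division", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "endpoint_table"))
  body <- x[x$kind == "body", ]
  if (!nrow(body)) stop("no body rows to correct", call. = FALSE)

  if (mode == "fresh_control_division") {
    feats <- feature_names(x)
    controls <- x[x$kind == "fresh_control", ]
    ckey <- paste(controls$participant, controls$day)
    dup <- unique(ckey[duplicated(ckey)])
    if (length(dup))
      stop("duplicate fresh control for participant-day ", dup[1],
           call. = FALSE)
    bkey <- paste(body$participant, body$day)
    missing_ctrl <- setdiff(unique(bkey), ckey)
    if (length(missing_ctrl))
      stop("missing fresh control for participant-day ", missing_ctrl[1],
           call. = FALSE)
    cm <- as.matrix(controls[, feats])
    if (any(cm <= 0))
      stop("non-positive control endpoint; cannot divide", call. = FALSE)
    idx <- match(bkey, ckey)
    body[, feats] <- as.matrix(body[, feats]) / cm[idx, , drop = FALSE]
  }

  out <- endpoint_table(body)
  attr(out, "drift_correction") <- mode
  out
}

#' Subset an endpoint table by day, region and sample kind
#'
#' @param x An [endpoint_table].
#' @param days,regions,kinds Values to keep; `NULL` keeps all. Requesting
#'   a label absent from the table is an error, as is a selection that
#'   leaves no rows.
#' @return The filtered [endpoint_table].
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config())
#' day1_ear <- subset_endpoints(sim$table, days = 1, regions = "ear",
#'                              kinds = "body")
#' nrow(day1_ear)  # 12 participants x 3 replicates = 36
subset_endpoints <- function(x, days = NULL, regions = NULL, kinds = NULL) {
  stopifnot(inherits(x, "endpoint_table"))
  keep <- rep(TRUE, nrow(x))
  check_present <- function(wanted, have, what) {
    absent <- setdiff(wanted, have)
    if (length(absent))
      stop("requested ", what, " not present: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!is.null(days)) {
    days <- as.integer(days)
    check_present(days, unique(x$day), "day(s)")
    keep <- keep & x$day %in% days
  }
  if (!is.null(regions)) {
    regions <- tolower(regions)
    check_present(regions, unique(x$region[!is.na(x$region)]), "region(s)")
    keep <- keep & !is.na(x$region) & x$region %in% regions
  }
  if (!is.null(kinds)) {
    check_present(kinds, unique(x$kind), "kind(s)")
    keep <- keep & x$kind %in% kinds
  }
  if (!any(keep))
    stop("empty selection: no rows match the requested subset",
         call. = FALSE)
  out <- x[keep, ]
  attr(out, "drift_correction") <- attr(x, "drift_correction")
  out
}
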