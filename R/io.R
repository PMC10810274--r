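#' Read and write endpoint tables as CSV
#'
#' Two dialects are supported. `wide` (canonical for analysis output) has
#' one row per fused sample: the five metadata columns followed by the
#' `d<device>_s<sensor>` feature columns. `long` has one row per
#' device-sensor reading with columns `participant, day, kind, region,
#' replicate, device, sensor, endpoint`; on reading, rows sharing a sample
#' key are fused into one feature vector (device 1 sensors first), and the
#' result is sorted canonically so row order in the file does not matter.
#' Empty `region`/`replicate` cells encode the missing values of control
#' rows. Values are written losslessly (shortest round-trip decimal
#' representation).
#'
#' @param path File path.
#' @param dialect `"wide"` or `"long"`.
#' @param x An [endpoint_table].
#' @return `read_endpoint_csv()` returns a validated [endpoint_table];
#'   `write_endpoint_csv()` returns `path` invisibly.
#' @export
read_endpoint_csv <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               na = ""))
  need <- c("participant", "day", "kind", "region", "replicate")
  if (dialect == "long") need <- c(need, "device", "sensor", "endpoint")
  miss <- setdiff(need, hdr)
  if (length(miss))
    stop("schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (dialect == "wide") {
    df <- readr::read_csv(path, col_types = readr::cols(
      participant = readr::col_character(),
      day = readr::col_integer(),
      kind = readr::col_character(),
      region = readr::col_character(),
      replicate = readr::col_integer(),
      .default = readr::col_double()), na = "")
    return(endpoint_table(df))
  }

  df <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    day = readr::col_integer(),
    kind = readr::col_character(),
    region = readr::col_character(),
    replicate = readr::col_integer(),
    device = readr::col_integer(),
    sensor = readr::col_integer(),
    endpoint = readr::col_double()), na = "")
  df$feature <- paste0("d", df$device, "_s", df$sensor)
  key <- c("participant", "day", "kind", "region", "replicate")
  dup <- duplicated(df[, c(key, "feature")])
  if (any(dup))
    stop("fusion error: duplicated device/sensor reading for sample key ",
         paste(unlist(df[which(dup)[1], key]), collapse = "/"),
         call. = FALSE)
  wide <- tidyr::pivot_wider(df[, c(key, "feature", "endpoint")],
                             names_from = "feature",
                             values_from = "endpoint")
  feats <- sort_feature_names(setdiff(names(wide), key))
  fm <- as.matrix(wide[, feats])
  if (anyNA(fm)) {
    bad <- which(rowSums(is.na(fm)) > 0)[1]
    stop("fusion error: device-incomplete sample for key ",
         paste(unlist(wide[bad, key]), collapse = "/"), call. = FALSE)
  }
  wide <- dplyr::arrange(wide, .data$participant, .data$day, .data$kind,
                         .data$region, .data$replicate)
  endpoint_table(wide)
}

#' @rdname read_endpoint_csv
#' @export
write_endpoint_csv <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "endpoint_table"))
  if (dialect == "wide") {
    readr::write_csv(tibble::as_tibble(x), path, na = "")
    return(invisible(path))
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              cols = tidyr::all_of(feature_names(x)),
                              names_to = "feature", values_to = "endpoint")
  long$device <- as.integer(sub("^d([0-9]+)_s[0-9]+$", "\\1", long$feature))
  long$sensor <- as.integer(sub("^d[0-9]+_s([0-9]+)$", "\\1", long$feature))
  long <- dplyr::arrange(
    long[, c("participant", "day", "kind", "region", "replicate",
             "device", "sensor", "endpoint")],
    .data$participant, .data$day, .data$kind, .data$region,
    .data$replicate, .data$device, .data$sensor)
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' Condense a measurement time series to sensor endpoints
#'
#' The endpoint of each channel is the value at the end of the measurement
#' phase: the final time sample, or the mean of the last `window` samples
#' when a smoothing window is requested.
#'
#' @param record A `measurement_record` with a `channels` matrix
#'   (sensors x time), e.g. from [simulate_time_series()].
#' @param window Number of trailing samples to average (default 1, the
#'   final sample alone).
#' @return The record with an `endpoints` vector added and the time series
#'   removed.
#' @export
extract_endpoints <- function(record, window = 1) {
  stopifnot(inherits(record, "measurement_record"))
  ch <- record$channels
  if (is.null(ch) || !is.matrix(ch) || ncol(ch) == 0)
    stop("record has no non-empty time series", call. = FALSE)
  if (window < 1 || window > ncol(ch))
    stop("window must be in [1, n_samples]", call. = FALSE)
  if (anyNA(ch[, ncol(ch)]))
    stop("NaN/NA in final time sample", call. = FALSE)
  idx <- (ncol(ch) - window + 1):ncol(ch)
  record$endpoints <- rowMeans(ch[, idx, drop = FALSE])
  record$channels <- NULL
  record$time <- NULL
  record
}

#' Fuse per-device measurement records into an endpoint table
#'
#' Groups records by sample key (participant, day, kind, region,
#' replicate), checks that every device 1..max(device) contributed exactly
#' one record, and concatenates their endpoints in device order into one
#' fused feature vector per sample.
#'
#' @param records List of `measurement_record`s carrying `endpoints`
#'   (see [extract_endpoints()]).
#' @return An [endpoint_table].
#' @export
fuse_endpoints <- function(records) {
  if (!length(records)) stop("no records to fuse", call. = FALSE)
  has_ep <- vapply(records, function(r) !is.null(r$endpoints), logical(1))
  if (!all(has_ep))
    stop("all records must carry endpoints (run extract_endpoints first)",
         call. = FALSE)
  keys <- vapply(records, function(r)
    paste(r$participant, r$day, r$kind, r$region, r$replicate, sep = "\r"),
    character(1))
  devices <- vapply(records, function(r) as.integer(r$device), integer(1))
  V <- max(devices)
  S <- length(records[[1]]$endpoints)

  groups <- split(seq_along(records), keys)
  # preserve first-appearance order of samples
  groups <- groups[order(vapply(groups, min, integer(1)))]
  rows <- lapply(groups, function(idx) {
    dv <- devices[idx]
    if (!setequal(dv, seq_len(V)) || anyDuplicated(dv))
      stop("fusion error: sample ", gsub("\r", "/", keys[idx[1]]),
           " is device-incomplete", call. = FALSE)
    r1 <- records[[idx[1]]]
    feat <- unlist(lapply(seq_len(V),
                          function(v) records[[idx[dv == v]]]$endpoints))
    tibble::tibble(participant = r1$participant, day = as.integer(r1$day),
                   kind = r1$kind,
                   region = if (is.null(r1$region)) NA_character_ else
                     r1$region,
                   replicate = if (is.null(r1$replicate)) NA_integer_ else
                     as.integer(r1$replicate),
                   !!!stats::setNames(as.list(feat),
                                      as.vector(vapply(seq_len(V), function(v)
                                        paste0("d", v, "_s", seq_len(S)),
                                        character(S)))))
  })
  endpoint_table(dplyr::bind_rows(rows))
}
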