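#' Endpoint tables: the pipeline's central exchange object
#'
#' An endpoint table is a tibble with one row per fused sample. Metadata
#' columns are `participant` (character), `day` (integer, 1-based), `kind`
#' (one of `body`, `fresh_control`, `overnight_control`, `baseline`,
#' `clean_cycle`), `region` (lower-case label for body rows, `NA`
#' otherwise) and `replicate` (integer for body rows, `NA` otherwise).
#' Feature columns are named `d<device>_s<sensor>` and hold strictly
#' positive sensor endpoints (conductivity ratios G0/G), ordered device 1
#' sensors 1..S, then device 2, and so on — the "fused" vector combining
#' all devices that measured the sample.
#'
#' @param x A data frame with the columns described above.
#' @return `endpoint_table()` returns a validated tibble of class
#'   `endpoint_table`.
#' @export
#' @examples
#' tbl <- endpoint_table(tibble::tibble(
#'   participant = "P01", day = 1L, kind = "body",
#'   region = "ear", replicate = 1L,
#'   d1_s1 = 1.2, d1_s2 = 0.8))
#' feature_names(tbl)
endpoint_table <- function(x) {
  x <- tibble::as_tibble(x)
  meta <- c("participant", "day", "kind", "region", "replicate")
  missing_cols <- setdiff(meta, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  feats <- grep("^d[0-9]+_s[0-9]+$", names(x), value = TRUE)
  if (!length(feats))
    stop("no feature columns (expected names like 'd1_s1')", call. = FALSE)

  x$participant <- as.character(x$participant)
  x$day <- as.integer(x$day)
  x$kind <- as.character(x$kind)
  x$region <- if (all(is.na(x$region))) NA_character_ else
    tolower(as.character(x$region))
  x$region[!is.na(x$region) & x$region == ""] <- NA_character_
  x$replicate <- as.integer(x$replicate)

  x <- x[, c(meta, sort_feature_names(feats))]
  validate_endpoint_table(x)
  class(x) <- unique(c("endpoint_table", class(tibble::tibble())))
  x
}

# canonical feature order: device, then sensor, numerically
sort_feature_names <- function(feats) {
  dv <- as.integer(sub("^d([0-9]+)_s[0-9]+$", "\\1", feats))
  sn <- as.integer(sub("^d[0-9]+_s([0-9]+)$", "\\1", feats))
  feats[order(dv, sn)]
}

valid_kinds <- c("body", "fresh_control", "overnight_control", "baseline",
                 "clean_cycle")

validate_endpoint_table <- function(x) {
  feats <- feature_names(x)
  dv <- as.integer(sub("^d([0-9]+)_s[0-9]+$", "\\1", feats))
  sn <- as.integer(sub("^d[0-9]+_s([0-9]+)$", "\\1", feats))
  grid <- table(dv)
  if (length(unique(grid)) > 1 ||
      !setequal(dv, seq_len(max(dv))) ||
      !all(tapply(sn, dv, function(s) setequal(s, seq_len(max(sn))))))
    stop("feature columns must form a complete device x sensor grid",
         call. = FALSE)

  bad_kind <- setdiff(unique(x$kind), valid_kinds)
  if (length(bad_kind))
    stop("unknown sample kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)

  fm <- as.matrix(x[, feats])
  if (nrow(fm)) {
    bad <- which(!is.finite(fm) | fm <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive or non-finite endpoint at row ", bad[1, 1],
           ", column ", feats[bad[1, 2]], call. = FALSE)
  }

  body <- x$kind == "body"
  if (any(body & (is.na(x$region) | is.na(x$replicate))))
    stop("body rows must carry region and replicate", call. = FALSE)
  if (any(!body & (!is.na(x$region) | !is.na(x$replicate))))
    stop("non-body rows must not carry region or replicate", call. = FALSE)

  key <- paste(x$participant, x$day, x$kind, x$region, x$replicate)
  if (anyDuplicated(key))
    stop("duplicated sample key: ", key[duplicated(key)][1], call. = FALSE)
  invisible(x)
}

#' @rdname endpoint_table
#' @export
feature_names <- function(x) {
  sort_feature_names(grep("^d[0-9]+_s[0-9]+$", names(x), value = TRUE))
}

#' @rdname endpoint_table
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(x[, feature_names(x)])
  rownames(m) <- NULL
  m
}

# number of devices / sensors encoded in the feature columns
table_devices <- function(x) {
  feats <- feature_names(x)
  max(as.integer(sub("^d([0-9]+)_s[0-9]+$", "\\1", feats)))
}

table_sensors <- function(x) {
  feats <- feature_names(x)
  max(as.integer(sub("^d[0-9]+_s([0-9]+)$", "\\1", feats)))
}
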