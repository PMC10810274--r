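#' Run the full identification pipeline on a cohort
#'
#' Orchestrates simulate (or load) -> drift-correct -> validate ->
#' permutation-test into one reproducible run. For each body region and
#' each drift mode it computes per-day leave-one-out accuracies, the
#' repeated leave-one-sample-per-participant-out distribution per day,
#' accumulated-day curves, the across-day holdout (train on all days but
#' the last, test on the last) and a permutation test on day 1. Stages
#' that need several days are skipped with a notice when the table has
#' only one day.
#'
#' @param config A [cohort_config()] describing the synthetic cohort, or
#'   an [endpoint_table] of already-loaded measurements (body +
#'   fresh-control rows).
#' @param model_config A [knn_config()] or [lda_config()].
#' @param n_iterations Iterations for the stochastic fold scheme.
#' @param n_null Null iterations for the permutation tests.
#' @param permutation_day Day on which the within-day permutation test is
#'   run (default 1).
#' @param seed Integer seed governing all randomized stages.
#' @param out_dir Optional directory: results are written as CSV, the
#'   run manifest as JSON, and the figures as one PDF.
#' @return A list of class `pipeline_result` with tibbles `within_day`,
#'   `accumulated`, `holdout`, a list `permutation` of
#'   `permutation_result`s keyed by region/drift, and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         model_config = knn_config(),
                         n_iterations = 500, n_null = 500,
                         permutation_day = 1,
                         seed = 1, out_dir = NULL) {
  if (inherits(config, "cohort_config")) {
    sim <- simulate_cohort(config)
    table <- sim$table
    source_desc <- "synthetic"
  } else if (inherits(config, "endpoint_table")) {
    table <- config
    source_desc <- "supplied table"
  } else stop("config must be a cohort_config or an endpoint_table",
              call. = FALSE)

  regions <- sort(unique(table$region[!is.na(table$region)]))
  days <- sort(unique(table$day))
  multi_day <- length(days) >= 2
  if (!multi_day)
    message("single-day table: accumulated-day and holdout stages skipped")

  drift_modes <- c(none = "none", corrected = "fresh_control_division")
  if (!any(table$kind == "fresh_control")) {
    message("no fresh-control rows: drift-corrected stages skipped")
    drift_modes <- drift_modes["none"]
  }

  within <- list(); accum <- list(); hold <- list(); perms <- list()
  for (dm in names(drift_modes)) {
    body <- drift_correct(table, mode = drift_modes[[dm]])
    for (reg in regions) {
      reg_tbl <- subset_endpoints(body, regions = reg)
      for (d in days) {
        day_tbl <- subset_endpoints(reg_tbl, days = d)
        loo <- run_loo(day_tbl, model_config)
        pers <- run_one_per_participant(
          day_tbl, model_config, n_iterations,
          seed = hash_seed(seed, paste("within", dm, reg, d)))
        within[[length(within) + 1]] <- tibble::tibble(
          drift = dm, region = reg, day = d,
          scheme = c("loo", "one_per_participant"),
          accuracy = c(loo$mean, pers$mean),
          sd = c(NA_real_, pers$sd))
      }
      if (permutation_day %in% days) {
        perm_tbl <- subset_endpoints(reg_tbl, days = permutation_day)
        perms[[paste(dm, reg, sep = "/")]] <- permutation_test(
          perm_tbl, model_config,
          fold_scheme("one_per_participant", n_iterations = n_iterations),
          n_null = n_null, seed = hash_seed(seed, paste("perm", dm, reg)))
      }
      if (multi_day) {
        day_sets <- lapply(2:length(days), function(k) days[seq_len(k)])
        acc <- run_accumulated_days(
          reg_tbl, model_config, day_sets, n_iterations,
          seed = hash_seed(seed, paste("accum", dm, reg)))
        accum[[length(accum) + 1]] <- tibble::tibble(
          drift = dm, region = reg,
          days = names(acc),
          n_days = vapply(day_sets, length, integer(1)),
          accuracy = vapply(acc, function(a) a$mean, numeric(1)),
          sd = vapply(acc, function(a) a$sd, numeric(1)))
        ho <- run_day_holdout(reg_tbl, model_config,
                              train_days = days[-length(days)],
                              test_day = days[length(days)])
        hold[[length(hold) + 1]] <- tibble::tibble(
          drift = dm, region = reg,
          train_days = paste(ho$train_days, collapse = ","),
          test_day = ho$test_day, accuracy = ho$accuracy,
          n_test = ho$n_test)
      }
    }
  }

  n_classes <- length(unique(table$participant[table$kind == "body"]))
  manifest <- list(
    package_version = as.character(utils::packageVersion("enoseid")),
    source = source_desc,
    config = if (inherits(config, "cohort_config"))
      unclass(config) else NULL,
    model = unclass(model_config),
    seed = seed, n_iterations = n_iterations, n_null = n_null,
    n_classes = n_classes, chance = 1 / n_classes,
    regions = regions, days = days,
    timestamp = format(Sys.time(), tz = "UTC"))

  res <- structure(list(
    within_day = dplyr::bind_rows(within),
    accumulated = if (length(accum)) dplyr::bind_rows(accum) else NULL,
    holdout = if (length(hold)) dplyr::bind_rows(hold) else NULL,
    permutation = perms,
    manifest = manifest), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$within_day, file.path(out_dir, "within_day.csv"))
  if (!is.null(res$accumulated))
    readr::write_csv(res$accumulated, file.path(out_dir, "accumulated.csv"))
  if (!is.null(res$holdout))
    readr::write_csv(res$holdout, file.path(out_dir, "holdout.csv"))
  if (length(res$permutation)) {
    perm_tbl <- dplyr::bind_rows(lapply(names(res$permutation), function(nm) {
      p <- res$permutation[[nm]]
      tibble::tibble(case = nm, observed_median = p$observed,
                     null_median = stats::median(p$null),
                     p_value = p$p_value, n_null = p$n_null)
    }))
    readr::write_csv(perm_tbl, file.path(out_dir, "permutation.csv"))
    null_tbl <- dplyr::bind_rows(lapply(names(res$permutation), function(nm)
      tibble::tibble(case = nm, iteration = seq_along(res$permutation[[nm]]$null),
                     null_accuracy = res$permutation[[nm]]$null)))
    readr::write_csv(null_tbl, file.path(out_dir, "null_accuracies.csv"))
  }
  manifest <- res$manifest
  csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest$outputs <- stats::setNames(as.list(unname(tools::md5sum(csvs))),
                                      basename(csvs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  figs <- report_figures(res)
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 8, height = 5)
  on.exit(grDevices::dev.off())
  for (f in figs) print(f)
  invisible(out_dir)
}

#' Render the pipeline's summary figures
#'
#' Produces ggplot analogues of the study's result panels: per-day
#' accuracy bars with the chance line at `1/C`, accumulated-day curves,
#' across-day holdout bars, and real-versus-null accuracy histograms with
#' median markers for each permutation test.
#'
#' @param res A `pipeline_result` from [run_pipeline()].
#' @return A named list of ggplot objects.
#' @export
report_figures <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  chance <- res$manifest$chance
  figs <- list()

  figs$within_day <- ggplot2::ggplot(
    dplyr::filter(res$within_day, .data$scheme == "loo"),
    ggplot2::aes(x = factor(.data$day), y = .data$accuracy,
                 fill = .data$drift)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "day", y = "leave-one-out accuracy",
                  title = "Within-day identification accuracy",
                  subtitle = sprintf("dashed line: chance = %.1f%%",
                                     100 * chance)) +
    ggplot2::ylim(0, 1)

  if (!is.null(res$accumulated))
    figs$accumulated <- ggplot2::ggplot(
      res$accumulated,
      ggplot2::aes(x = .data$n_days, y = .data$accuracy,
                   colour = .data$region, linetype = .data$drift,
                   group = interaction(.data$region, .data$drift))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
      ggplot2::labs(x = "days accumulated", y = "mean accuracy",
                    title = "Accumulated-day identification accuracy") +
      ggplot2::ylim(0, 1)

  if (!is.null(res$holdout))
    figs$holdout <- ggplot2::ggplot(
      res$holdout,
      ggplot2::aes(x = .data$region, y = .data$accuracy,
                   fill = .data$drift)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
      ggplot2::labs(x = NULL, y = "holdout accuracy",
                    title = "Across-day holdout (unseen test day)") +
      ggplot2::ylim(0, 1)

  if (length(res$permutation)) {
    for (nm in names(res$permutation)) {
      p <- res$permutation[[nm]]
      if (!length(p$null))
        stop("permutation result '", nm, "' has an empty null distribution",
             call. = FALSE)
      df <- rbind(
        data.frame(accuracy = p$real$accuracies, which = "real"),
        data.frame(accuracy = p$null, which = "null"))
      figs[[paste0("permutation_", gsub("/", "_", nm))]] <-
        ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy,
                                         fill = .data$which)) +
        ggplot2::geom_histogram(alpha = 0.6, position = "identity",
                                bins = 30) +
        ggplot2::geom_vline(xintercept = p$observed, linetype = "dashed") +
        ggplot2::geom_vline(xintercept = stats::median(p$null),
                            linetype = "dotted") +
        ggplot2::labs(title = paste0("Real vs null accuracies: ", nm),
                      subtitle = sprintf("permutation p = %.4g", p$p_value),
                      x = "accuracy")
    }
  }
  figs
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  within-day rows:", nrow(x$within_day), "\n")
  if (!is.null(x$accumulated))
    cat("  accumulated rows:", nrow(x$accumulated), "\n")
  if (!is.null(x$holdout))
    cat("  holdout rows:", nrow(x$holdout), "\n")
  cat("  permutation tests:", length(x$permutation), "\n")
  invisible(x)
}
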