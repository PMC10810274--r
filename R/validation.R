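#' Accuracy distributions over repeated validation runs
#'
#' Bundles the per-iteration accuracies of a validation design with its
#' summary statistics: the mean (reported as the design's accuracy), the
#' median (the summary the permutation test compares against its null) and
#' the standard deviation.
#'
#' @param accuracies Numeric vector of per-iteration accuracies in [0, 1].
#' @param scheme Character description of the validation design.
#' @return An object of class `accuracy_distribution`.
#' @export
accuracy_distribution <- function(accuracies, scheme = "unspecified") {
  accuracies <- as.numeric(accuracies)
  if (!length(accuracies) || any(accuracies < 0 | accuracies > 1))
    stop("accuracies must be proportions in [0, 1]", call. = FALSE)
  structure(list(accuracies = accuracies,
                 mean = mean(accuracies),
                 median = stats::median(accuracies),
                 sd = stats::sd(accuracies),
                 n_iterations = length(accuracies),
                 scheme = scheme),
            class = "accuracy_distribution")
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat(sprintf("<accuracy_distribution> %s: mean %.3f, median %.3f, sd %s (%d iteration%s)\n",
              x$scheme, x$mean, x$median,
              if (is.na(x$sd)) "NA" else sprintf("%.3f", x$sd),
              x$n_iterations, if (x$n_iterations == 1) "" else "s"))
  invisible(x)
}

# body-only feature matrix + participant labels
table_to_xy <- function(x) {
  stopifnot(inherits(x, "endpoint_table"))
  if (any(x$kind != "body"))
    stop("validation expects a body-sample table; drop control rows first ",
         "(see drift_correct or subset_endpoints)", call. = FALSE)
  list(x = feature_matrix(x), y = factor(x$participant))
}

# can distances be precomputed once and reused across folds?
knn_fast <- function(config) {
  inherits(config, "knn_config") && !config$standardize
}

# evaluate one train/test split, returning predicted labels (character)
eval_split <- function(x, y, train, test, config, d2 = NULL) {
  if (!is.null(d2)) {
    excl <- setdiff(seq_len(nrow(x)), train)
    return(vapply(test, function(i)
      knn_vote(d2[i, ], y, config$k, exclude = excl), character(1)))
  }
  fit <- fit_classifier(x[train, , drop = FALSE], y[train], config)
  as.character(predict(fit, x[test, , drop = FALSE]))
}

#' Leave-one-out cross-validation accuracy
#'
#' Holds out each sample in turn, trains on the remainder, and reports the
#' fraction of held-out samples assigned to the correct participant.
#' Deterministic: the result is a degenerate [accuracy_distribution] with
#' a single entry.
#'
#' @param x An [endpoint_table] of body samples (typically one day and one
#'   region, e.g. 12 participants x 3 replicates = 36 samples).
#' @param config A [knn_config()] or [lda_config()].
#' @return An [accuracy_distribution] with one accuracy value.
#' @export
run_loo <- function(x, config = knn_config()) {
  xy <- table_to_xy(x)
  N <- nrow(xy$x)
  if (N < 2) stop("need at least 2 samples for leave-one-out", call. = FALSE)
  d2 <- if (knn_fast(config)) cross_dist2(xy$x, xy$x)
  correct <- vapply(seq_len(N), function(i) {
    pred <- eval_split(xy$x, xy$y, setdiff(seq_len(N), i), i, config, d2)
    pred == as.character(xy$y[i])
  }, logical(1))
  accuracy_distribution(mean(correct), scheme = "loo")
}

#' Random fold assignment for leave-one-sample-per-participant-out CV
#'
#' Each participant's `m` samples are randomly permuted into `m` folds, so
#' every fold holds out exactly one sample per participant and every
#' sample is tested exactly once per iteration.
#'
#' @param y Participant label per sample (all counts must be equal).
#' @param seed,iteration Stream identifiers; the assignment is a
#'   deterministic function of both.
#' @return Integer fold id (1..m) per sample.
#' @export
persample_folds <- function(y, seed = 1, iteration = 1) {
  y <- factor(y)
  counts <- table(y)
  m <- unique(as.integer(counts))
  if (length(m) != 1)
    stop("unequal replicate counts per participant: ",
         paste(range(counts), collapse = " vs "), call. = FALSE)
  folds <- integer(length(y))
  with_stream(seed, paste0("iter/", iteration), {
    for (p in levels(y)) {
      idx <- which(y == p)
      folds[idx] <- sample(m)
    }
    folds
  })
}

#' Repeated leave-one-sample-per-participant-out cross-validation
#'
#' The stricter within-day design: with `m` samples per participant, each
#' iteration randomly assigns every participant's samples to `m` folds;
#' each fold trains on `m - 1` samples per participant and tests on the
#' remaining one per participant. The iteration's accuracy is the fraction
#' of all samples predicted correctly across folds; repeating over
#' `n_iterations` random assignments yields the accuracy distribution
#' whose mean is reported as the design's accuracy.
#'
#' @param x An [endpoint_table] of body samples with equal per-participant
#'   counts.
#' @param config A [knn_config()] or [lda_config()].
#' @param n_iterations Number of random fold assignments (default 500).
#' @param seed Integer seed; identical seeds give identical results.
#' @return An [accuracy_distribution] of length `n_iterations`.
#' @export
run_one_per_participant <- function(x, config = knn_config(),
                                    n_iterations = 500, seed = 1) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  xy <- table_to_xy(x)
  d2 <- if (knn_fast(config)) cross_dist2(xy$x, xy$x)
  acc <- vapply(seq_len(n_iterations), function(it) {
    folds <- persample_folds(xy$y, seed, it)
    one_persample_pass(xy$x, xy$y, folds, config, d2)
  }, numeric(1))
  accuracy_distribution(acc, scheme = "one_per_participant")
}

# one full pass over a fold assignment; returns overall fraction correct
one_persample_pass <- function(x, y, folds, config, d2 = NULL) {
  correct <- logical(length(y))
  for (j in sort(unique(folds))) {
    test <- which(folds == j)
    train <- which(folds != j)
    pred <- eval_split(x, y, train, test, config, d2)
    correct[test] <- pred == as.character(y[test])
  }
  mean(correct)
}

#' Accumulated-days cross-validation
#'
#' Runs [run_one_per_participant()] on growing day ranges. With `k` days
#' and `r` replicates per day, each participant contributes `m = k * r`
#' samples, so folds train on `m - 1` and test on 1 sample per
#' participant — the fold count grows with the data to keep the
#' one-held-out-per-participant stringency constant (on 2 days: train 5,
#' test 1; on 4 days: train 11, test 1).
#'
#' @param x An [endpoint_table] of body samples spanning the listed days.
#' @param config A [knn_config()] or [lda_config()].
#' @param day_sets List of integer day vectors (default `1:2` .. `1:5`).
#' @param n_iterations,seed Passed to [run_one_per_participant()].
#' @return Named list of [accuracy_distribution]s, one per day set.
#' @export
run_accumulated_days <- function(x, config = knn_config(),
                                 day_sets = list(1:2, 1:3, 1:4, 1:5),
                                 n_iterations = 500, seed = 1) {
  res <- lapply(seq_along(day_sets), function(i) {
    days <- day_sets[[i]]
    sub <- subset_endpoints(x, days = days)
    out <- run_one_per_participant(sub, config, n_iterations,
                                   seed = hash_seed(seed, paste0("days/",
                                     paste(days, collapse = ","))))
    out$scheme <- paste0("one_per_participant/days",
                         paste(range(days), collapse = "-"))
    out
  })
  names(res) <- vapply(day_sets, function(d)
    paste0("days", paste(range(d), collapse = "-")), character(1))
  res
}

#' Across-day holdout: train on some days, test on an unseen day
#'
#' Fits the classifier once on all body samples of the training days and
#' reports the fraction of the held-out day's samples identified
#' correctly. Deterministic.
#'
#' @param x An [endpoint_table] of body samples covering the requested
#'   days.
#' @param config A [knn_config()] or [lda_config()].
#' @param train_days Integer vector of training days.
#' @param test_day Single held-out day, not among `train_days`.
#' @return A list of class `holdout_result` with `accuracy`, `n_test`,
#'   `predicted` and `truth`.
#' @export
run_day_holdout <- function(x, config = knn_config(),
                            train_days = 1:4, test_day = 5) {
  if (length(test_day) != 1)
    stop("test_day must be a single day", call. = FALSE)
  if (test_day %in% train_days)
    stop("test_day must not be among train_days", call. = FALSE)
  train_tbl <- subset_endpoints(x, days = train_days)
  test_tbl <- subset_endpoints(x, days = test_day)
  xy_train <- table_to_xy(train_tbl)
  xy_test <- table_to_xy(test_tbl)
  fit <- fit_classifier(xy_train$x, xy_train$y, config)
  pred <- as.character(predict(fit, xy_test$x))
  truth <- as.character(xy_test$y)
  structure(list(accuracy = mean(pred == truth),
                 n_test = length(truth),
                 predicted = pred, truth = truth,
                 train_days = train_days, test_day = test_day),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf("<holdout_result> train days {%s} -> test day %d: accuracy %.3f (%d samples)\n",
              paste(x$train_days, collapse = ","), x$test_day,
              x$accuracy, x$n_test))
  invisible(x)
}

#' Declarative description of a validation design
#'
#' A small descriptor consumed by [permutation_test()] and
#' [run_pipeline()], naming one of the three fold designs and its
#' parameters.
#'
#' @param kind `"loo"`, `"one_per_participant"` or `"day_holdout"`.
#' @param n_iterations Iterations for the stochastic design (ignored by
#'   the deterministic ones).
#' @param train_days,test_day Days for the holdout design.
#' @return A list of class `fold_scheme`.
#' @export
fold_scheme <- function(kind = c("loo", "one_per_participant",
                                 "day_holdout"),
                        n_iterations = 500, train_days = 1:4,
                        test_day = 5) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_iterations = n_iterations,
                 train_days = train_days, test_day = test_day),
            class = "fold_scheme")
}

# run a scheme on a (possibly label-shuffled) table copy; returns either a
# full accuracy_distribution (shuffle = NULL) or a single accuracy value
# for one pass with the given labels
run_scheme <- function(x, config, scheme, seed) {
  switch(scheme$kind,
    loo = run_loo(x, config),
    one_per_participant = run_one_per_participant(
      x, config, n_iterations = scheme$n_iterations, seed = seed),
    day_holdout = {
      h <- run_day_holdout(x, config, scheme$train_days, scheme$test_day)
      accuracy_distribution(h$accuracy, scheme = "day_holdout")
    })
}
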