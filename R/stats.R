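#' Exact binomial identification statistics
#'
#' For a closed-set identification task over `n` participants, the chance
#' probability of identifying one person correctly is `p_chance = 1/n`
#' (0.0833 for a 12-person roster). `binomial_point_p()` gives the exact
#' point probability of observing `r` correct identifications out of `n`
#' trials by chance,
#' \deqn{P(r) = \binom{n}{r} p^r (1-p)^{n-r},}
#' evaluated in log-gamma arithmetic. `accuracy_to_r()` converts a
#' classification accuracy to the equivalent number correct out of `n`,
#' rounding half away from zero (0.87 on 12 trials is 10 of 12).
#'
#' @param r Number of correct identifications (0..n).
#' @param n Number of identification trials.
#' @param p_chance Per-trial chance success probability in (0, 1).
#' @return `binomial_point_p()` returns the exact point probability;
#'   `accuracy_to_r()` an integer count.
#' @export
#' @examples
#' binomial_point_p(10, 12, 1 / 12)   # far below 1e-5
#' accuracy_to_r(0.87, 12)            # 10
binomial_point_p <- function(r, n, p_chance) {
  if (any(r != floor(r)) || any(n != floor(n)))
    stop("r and n must be integers", call. = FALSE)
  if (any(r < 0) || any(r > n))
    stop("r must satisfy 0 <= r <= n", call. = FALSE)
  if (any(p_chance <= 0) || any(p_chance > 1))
    stop("p_chance must be in (0, 1]", call. = FALSE)
  stats::dbinom(r, n, p_chance)
}

#' @rdname binomial_point_p
#' @param accuracy Proportion correct in [0, 1].
#' @export
accuracy_to_r <- function(accuracy, n) {
  if (any(accuracy < 0) || any(accuracy > 1))
    stop("accuracy must be in [0, 1]", call. = FALSE)
  as.integer(floor(accuracy * n + 0.5))
}

#' Permutation test of identification accuracy
#'
#' Builds a null distribution by repeatedly shuffling the participant
#' labels across all samples of the evaluation table, re-running the
#' validation design on the shuffled labels, and recording the resulting
#' accuracy. The observed summary is the median of the real accuracy
#' distribution; the p-value uses the add-one estimator
#' \deqn{p = \frac{1 + \#\{ \mathrm{null} \ge \mathrm{observed} \}}
#'                {1 + n_{\mathrm{null}}},}
#' whose floor with 500 null iterations is 1/501, printing as 0.002.
#'
#' Shuffling happens before fold construction and fitting, so the null
#' model is trained on genuinely scrambled data. Distances between samples
#' are unaffected by label shuffling, so the KNN fast path reuses one
#' distance matrix across all null iterations.
#'
#' @param x An [endpoint_table] of body samples.
#' @param config A [knn_config()] or [lda_config()].
#' @param scheme A [fold_scheme()].
#' @param n_null Number of null (label-shuffled) iterations, default 500.
#' @param seed Integer seed for both the real and null randomizations.
#' @return A list of class `permutation_result` with `observed` (median of
#'   the real distribution), `real` (the real [accuracy_distribution]),
#'   `null` (numeric vector of null accuracies), `p_value` and `n_null`.
#' @export
permutation_test <- function(x, config = knn_config(),
                             scheme = fold_scheme("one_per_participant"),
                             n_null = 500, seed = 1) {
  if (n_null < 1) stop("n_null must be >= 1", call. = FALSE)
  stopifnot(inherits(scheme, "fold_scheme"))
  real <- run_scheme(x, config, scheme, seed = hash_seed(seed, "real"))
  observed <- real$median

  xy <- table_to_xy(x)
  d2 <- if (knn_fast(config)) cross_dist2(xy$x, xy$x)
  null_acc <- vapply(seq_len(n_null), function(it) {
    y_perm <- stream_shuffle(xy$y, seed, paste0("null/", it))
    null_pass(xy$x, y_perm, x$day, config, scheme,
              seed = hash_seed(seed, paste0("nullfold/", it)), d2 = d2)
  }, numeric(1))

  p <- (1 + sum(null_acc >= observed)) / (1 + n_null)
  structure(list(observed = observed, real = real, null = null_acc,
                 p_value = p, n_null = n_null, scheme = scheme),
            class = "permutation_result")
}

# one evaluation pass of a scheme with (shuffled) labels y on features x
null_pass <- function(x, y, day, config, scheme, seed, d2 = NULL) {
  N <- nrow(x)
  switch(scheme$kind,
    loo = mean(vapply(seq_len(N), function(i) {
      pred <- eval_split(x, y, setdiff(seq_len(N), i), i, config, d2)
      pred == as.character(y[i])
    }, logical(1))),
    one_per_participant = {
      folds <- persample_folds(y, seed, 1)
      one_persample_pass(x, y, folds, config, d2)
    },
    day_holdout = {
      train <- which(day %in% scheme$train_days)
      test <- which(day == scheme$test_day)
      if (!length(train) || !length(test))
        stop("holdout days not present in table", call. = FALSE)
      pred <- eval_split(x, y, train, test, config, d2)
      mean(pred == as.character(y[test]))
    })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed median %.3f vs %d null iterations (null median %.3f): p = %.4g\n",
              x$observed, x$n_null, stats::median(x$null), x$p_value))
  invisible(x)
}
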