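#' Classifier configurations
#'
#' The two models the identification analyses rest on, with fully
#' deterministic behaviour.
#'
#' `knn_config()` describes a k-nearest-neighbour classifier on Euclidean
#' distances over the raw fused features (k = 2 by default, the "fine"
#' KNN setting used throughout). Ties are resolved deterministically: when
#' the k nearest neighbours split their votes, the label of the nearer
#' neighbour among the tied classes wins; exactly equidistant neighbours
#' are ordered by training-row index.
#'
#' `lda_config()` describes linear discriminant analysis with a pooled
#' within-class covariance (divisor N - C), a small ridge added to its
#' diagonal for numerical stability, and empirical class priors. The
#' predicted class maximizes the linear discriminant
#' \deqn{\delta_c(x) = x^\top \Sigma^{-1} \mu_c -
#'   \tfrac12 \mu_c^\top \Sigma^{-1} \mu_c + \log \pi_c.}
#'
#' @param k Number of neighbours (>= 1, < training-set size).
#' @param standardize Centre and scale features by training mean/sd before
#'   computing distances. Off by default: endpoints are already on a
#'   common conductivity-ratio scale.
#' @param gamma Ridge added to the diagonal of the pooled covariance;
#'   `NULL` (default) uses `1e-6 * mean(diag(covariance))`.
#' @return A config object of class `knn_config` or `lda_config`.
#' @export
knn_config <- function(k = 2L, standardize = FALSE) {
  if (length(k) != 1 || k < 1 || k != floor(k))
    stop("k must be a positive integer", call. = FALSE)
  structure(list(kind = "knn", k = as.integer(k),
                 standardize = isTRUE(standardize)),
            class = c("knn_config", "model_config"))
}

#' @rdname knn_config
#' @export
lda_config <- function(gamma = NULL) {
  if (!is.null(gamma) && (length(gamma) != 1 || gamma < 0))
    stop("gamma must be a scalar >= 0", call. = FALSE)
  structure(list(kind = "lda", gamma = gamma),
            class = c("lda_config", "model_config"))
}

#' Fit an identification classifier
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class labels (participant ids), one per row of `x`.
#' @param config A [knn_config()] or [lda_config()].
#' @return A fitted model of class `enose_knn` or `enose_lda`; prediction
#'   with [predict()] is a pure function of the fit and the query.
#' @export
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
#' y <- c("a", "a", "b", "b")
#' fit <- fit_classifier(x, y, knn_config(k = 1))
#' predict(fit, rbind(c(0.2, 0.5), c(3.9, 0.5)))
fit_classifier <- function(x, y, config) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y))
    stop("x and y lengths differ", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2)
    stop("need at least 2 classes", call. = FALSE)
  if (anyNA(x)) stop("features must be finite", call. = FALSE)

  if (inherits(config, "knn_config")) {
    if (config$k >= nrow(x))
      stop("k must be smaller than the training-set size", call. = FALSE)
    center <- scale_sd <- NULL
    if (config$standardize) {
      center <- colMeans(x)
      scale_sd <- apply(x, 2, stats::sd)
      scale_sd[scale_sd == 0] <- 1
      x <- sweep(sweep(x, 2, center), 2, scale_sd, "/")
    }
    return(structure(list(x = x, y = y, k = config$k,
                          center = center, scale = scale_sd,
                          config = config),
                     class = c("enose_knn", "enose_fit")))
  }

  if (inherits(config, "lda_config")) {
    d <- ncol(x); n <- nrow(x); C <- nlevels(y)
    counts <- tabulate(y, C)
    if (n - C < 1)
      stop("need more samples than classes for a pooled covariance",
           call. = FALSE)
    means <- matrix(NA_real_, C, d)
    Sw <- matrix(0, d, d)
    for (c in seq_len(C)) {
      xc <- x[y == levels(y)[c], , drop = FALSE]
      means[c, ] <- colMeans(xc)
      dev <- sweep(xc, 2, means[c, ])
      Sw <- Sw + crossprod(dev)
    }
    Sw <- Sw / (n - C)
    gamma <- config$gamma %||% (1e-6 * mean(diag(Sw)))
    Sigma <- Sw + diag(gamma, d)
    R <- tryCatch(chol(Sigma), error = function(e)
      stop("pooled covariance is singular even after ridge; ",
           "increase gamma", call. = FALSE))
    Sinv <- chol2inv(R)
    A <- Sinv %*% t(means)                       # d x C discriminant weights
    b <- -0.5 * colSums(t(means) * A) + log(counts / n)
    return(structure(list(levels = levels(y), A = A, b = b,
                          means = means, gamma = gamma, d = d,
                          config = config),
                     class = c("enose_lda", "enose_fit")))
  }
  stop("unknown classifier config", call. = FALSE)
}

# squared Euclidean cross-distances, queries x training rows
cross_dist2 <- function(q, x) {
  d2 <- outer(rowSums(q * q), rep(1, nrow(x))) +
    outer(rep(1, nrow(q)), rowSums(x * x)) - 2 * tcrossprod(q, x)
  pmax(d2, 0)
}

# vote among the k nearest of one distance vector; candidates ordered by
# (distance, training index); vote ties fall back to the nearest neighbour
# whose class is among the tied leaders
knn_vote <- function(dvec, y, k, exclude = integer(0)) {
  idx <- seq_along(dvec)
  if (length(exclude)) {
    idx <- idx[-exclude]
    dvec <- dvec[idx]
  }
  ord <- idx[order(dvec, idx)][seq_len(k)]
  votes <- table(factor(y[ord], levels = levels(y)))
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) return(top)
  for (i in ord) if (as.character(y[i]) %in% top) return(as.character(y[i]))
}

#' @export
predict.enose_knn <- function(object, newdata, ...) {
  q <- as.matrix(newdata)
  if (ncol(q) != ncol(object$x))
    stop("query dimension (", ncol(q), ") does not match training (",
         ncol(object$x), ")", call. = FALSE)
  if (!is.null(object$center))
    q <- sweep(sweep(q, 2, object$center), 2, object$scale, "/")
  d2 <- cross_dist2(q, object$x)
  out <- vapply(seq_len(nrow(q)), function(i)
    knn_vote(d2[i, ], object$y, object$k), character(1))
  factor(out, levels = levels(object$y))
}

#' @export
predict.enose_lda <- function(object, newdata, ...) {
  q <- as.matrix(newdata)
  if (ncol(q) != object$d)
    stop("query dimension (", ncol(q), ") does not match training (",
         object$d, ")", call. = FALSE)
  scores <- q %*% object$A + matrix(object$b, nrow(q), length(object$b),
                                    byrow = TRUE)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}
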