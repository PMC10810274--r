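# Independent brute-force oracles used to check the classifiers and the
# binomial machinery. Deliberately written as plain loops over
# definitions, not sharing code with the implementation.

# KNN by exhaustive distance enumeration. Candidate order: increasing
# Euclidean distance, training-row index breaking exact ties. Vote ties
# resolved in favour of the class of the first candidate belonging to a
# top-voted class.
oracle_knn <- function(train_x, train_y, query, k) {
  train_y <- as.character(train_y)
  d <- numeric(nrow(train_x))
  for (i in seq_len(nrow(train_x)))
    d[i] <- sqrt(sum((train_x[i, ] - query)^2))
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(k)]
  votes <- table(train_y[nn])
  winners <- names(votes)[votes == max(votes)]
  for (i in nn) if (train_y[i] %in% winners) return(train_y[i])
}

# LDA by direct evaluation of the discriminant with solve() on an
# explicitly accumulated pooled covariance (divisor N - C).
oracle_lda <- function(train_x, train_y, query, gamma = NULL) {
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  d <- ncol(train_x); n <- nrow(train_x)
  Sw <- matrix(0, d, d)
  mus <- list()
  for (cl in classes) {
    xc <- train_x[train_y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    mus[[cl]] <- mu
    for (i in seq_len(nrow(xc)))
      Sw <- Sw + tcrossprod(xc[i, ] - mu)
  }
  Sw <- Sw / (n - length(classes))
  if (is.null(gamma)) gamma <- 1e-6 * mean(diag(Sw))
  Sigma <- Sw + diag(gamma, d)
  delta <- vapply(classes, function(cl) {
    mu <- mus[[cl]]
    a <- solve(Sigma, mu)
    sum(query * a) - 0.5 * sum(mu * a) +
      log(sum(train_y == cl) / n)
  }, numeric(1))
  classes[which.max(delta)]
}

# Exact binomial point probability by enumerating all 2^n outcome
# vectors (feasible for n <= 12).
oracle_binom <- function(r, n, p) {
  total <- 0
  for (m in 0:(2^n - 1)) {
    s <- sum(as.integer(intToBits(m))[1:n])
    if (s == r) total <- total + p^s * (1 - p)^(n - s)
  }
  total
}

# random small classification instance with a guaranteed >= 2 classes and
# >= 2 samples per class (so LDA's pooled covariance is defined)
random_instance <- function(n_classes = NULL, d = NULL, per_class = NULL) {
  n_classes <- n_classes %||% sample(2:4, 1)
  d <- d %||% sample(2:5, 1)
  per_class <- per_class %||% sample(2:6, 1)
  centers <- matrix(rnorm(n_classes * d, sd = 2), n_classes, d)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(c)
    centers[rep(c, per_class), , drop = FALSE] +
      matrix(rnorm(per_class * d), per_class, d)))
  y <- rep(sprintf("c%02d", seq_len(n_classes)), each = per_class)
  q <- matrix(rnorm(3 * d, sd = 2), 3, d)
  list(x = x, y = y, q = q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
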