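test_that("KNN and LDA match brute-force oracles on random small instances", {
  set.seed(101)
  for (rep in 1:60) {
    inst <- random_instance()
    for (k in 1:2) {
      fit <- fit_classifier(inst$x, inst$y, knn_config(k = k))
      pred <- as.character(predict(fit, inst$q))
      orac <- apply(inst$q, 1, function(q)
        oracle_knn(inst$x, inst$y, q, k))
      expect_identical(pred, unname(orac))
    }
    fit <- fit_classifier(inst$x, inst$y, lda_config())
    pred <- as.character(predict(fit, inst$q))
    orac <- apply(inst$q, 1, function(q) oracle_lda(inst$x, inst$y, q))
    expect_identical(pred, unname(orac))
  }
})

test_that("KNN decision rules are deterministic and as documented", {
  x <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  y <- c("a", "a", "b", "b")

  # query equal to a training point, k = 1 -> that point's label
  fit1 <- fit_classifier(x, y, knn_config(k = 1))
  expect_equal(as.character(predict(fit1, x)), y)

  # k = 2 with disagreeing neighbours -> the nearer neighbour's label
  fit2 <- fit_classifier(x, y, knn_config(k = 2))
  expect_equal(as.character(predict(fit2, rbind(c(5, 0)))), "a")  # 1 < 5
  expect_equal(as.character(predict(fit2, rbind(c(6.4, 0)))), "b")

  # exactly equidistant neighbours -> smallest training-row index wins
  xx <- rbind(c(-1, 0), c(1, 0))
  fit_t <- fit_classifier(xx, c("p", "q"), knn_config(k = 1))
  expect_equal(as.character(predict(fit_t, rbind(c(0, 0)))), "p")
  fit_t2 <- fit_classifier(xx[2:1, ], c("q", "p"), knn_config(k = 1))
  expect_equal(as.character(predict(fit_t2, rbind(c(0, 0)))), "q")
})

test_that("training-row order never changes predictions", {
  set.seed(202)
  for (rep in 1:10) {
    inst <- random_instance()
    perm <- sample(nrow(inst$x))
    for (cfg in list(knn_config(k = 1), knn_config(k = 2), lda_config())) {
      p1 <- predict(fit_classifier(inst$x, inst$y, cfg), inst$q)
      p2 <- predict(fit_classifier(inst$x[perm, ], inst$y[perm], cfg),
                    inst$q)
      expect_equal(as.character(p1), as.character(p2))
    }
  }
})

test_that("KNN k=1 self-prediction is perfect on distinct points", {
  set.seed(303)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("a", "b", "c", "d"), 5)
  fit <- fit_classifier(x, y, knn_config(k = 1))
  expect_equal(as.character(predict(fit, x)), y)
})

test_that("LDA with spherical classes is the nearest-centroid bisector", {
  # symmetric clouds around two means: pooled covariance is spherical,
  # priors equal, so the boundary is the perpendicular bisector
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  mu1 <- c(0, 0); mu2 <- c(6, 2)
  x <- rbind(sweep(offs, 2, mu1, "+"), sweep(offs, 2, mu2, "+"))
  y <- rep(c("a", "b"), each = 4)
  fit <- fit_classifier(x, y, lda_config(gamma = 0))
  q <- rbind(mu1 + 0.3 * (mu2 - mu1),   # nearer mu1
             mu1 + 0.7 * (mu2 - mu1))   # nearer mu2
  expect_equal(as.character(predict(fit, q)), c("a", "b"))
})

test_that("LDA predictions are invariant to invertible affine feature maps", {
  set.seed(404)
  for (rep in 1:5) {
    inst <- random_instance(n_classes = 3, d = 3, per_class = 6)
    repeat {
      A <- matrix(rnorm(9), 3, 3)
      if (abs(det(A)) > 0.5 && kappa(A) < 20) break
    }
    b <- rnorm(3)
    tx <- sweep(inst$x %*% A, 2, b, "+")
    tq <- sweep(inst$q %*% A, 2, b, "+")
    p1 <- predict(fit_classifier(inst$x, inst$y, lda_config(gamma = 0)),
                  inst$q)
    p2 <- predict(fit_classifier(tx, inst$y, lda_config(gamma = 0)), tq)
    expect_equal(as.character(p1), as.character(p2))
  }
})

test_that("LDA agrees with an established reference on separated classes", {
  skip_if_not_installed("MASS")
  set.seed(505)
  inst <- random_instance(n_classes = 3, d = 4, per_class = 8)
  inst$x[, 1] <- inst$x[, 1] + 5 * as.integer(factor(inst$y))
  ours <- predict(fit_classifier(inst$x, inst$y, lda_config(gamma = 0)),
                  inst$q)
  ref <- predict(MASS::lda(inst$x, grouping = inst$y), inst$q)$class
  expect_equal(as.character(ours), as.character(ref))
})

test_that("degenerate fits are rejected with clear messages", {
  x <- matrix(rnorm(12), 6, 2)
  y <- rep(c("a", "b"), 3)
  expect_error(fit_classifier(x, y, knn_config(k = 6)), "smaller")
  expect_error(fit_classifier(x, rep("a", 6), knn_config()), "2 classes")
  fit <- fit_classifier(x, y, knn_config(k = 1))
  expect_error(predict(fit, matrix(0, 1, 3)), "dimension")

  # duplicated feature column: singular pooled covariance at gamma = 0
  xs <- cbind(x[, 1], x[, 1])
  expect_error(fit_classifier(xs, y, lda_config(gamma = 0)), "gamma")
})
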