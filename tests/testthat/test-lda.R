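# Brute-force oracles built from first principles (explicit inversion,
# full normal densities, explicit refit loops).

oracle_pooled <- function(x, labels) {
  labels <- factor(labels)
  g <- nlevels(labels)
  w <- matrix(0, ncol(x), ncol(x))
  means <- matrix(NA, g, ncol(x), dimnames = list(levels(labels), NULL))
  for (cl in levels(labels)) {
    xg <- x[labels == cl, , drop = FALSE]
    means[cl, ] <- colMeans(xg)
    w <- w + t(sweep(xg, 2, colMeans(xg))) %*% sweep(xg, 2, colMeans(xg))
  }
  list(means = means, w = w / (nrow(x) - g))
}

test_that("two classes in one dimension give the closed-form boundary", {
  x <- matrix(c(0, 1, 2, 6, 7, 8), ncol = 1)
  lab <- rep(c("a", "b"), each = 3)
  m <- fit_lda(x, lab)
  expect_equal(ncol(m$axes), 1L)
  # equal priors: the midpoint of the class means is exactly ambiguous
  mid <- mean(m$class_means)
  p <- classify_lda(m, mid)$probabilities
  expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(classify_lda(m, mid - 0.1)$predicted,
               factor("a", levels = c("a", "b")))

  # equal class means: no discriminating power
  set.seed(1)
  x2 <- matrix(rnorm(40), ncol = 2)
  m2 <- fit_lda(x2, rep(c("a", "b"), 10))
  expect_lt(max(m2$axis_eigenvalues) / (1 + max(m2$axis_eigenvalues)), 0.25)
})

test_that("discriminant axes solve the between-within eigenproblem", {
  set.seed(2)
  n_per <- 10
  x <- rbind(matrix(rnorm(n_per * 3), ncol = 3),
             matrix(rnorm(n_per * 3), ncol = 3) + c(2, 0, 0),
             matrix(rnorm(n_per * 3), ncol = 3) + c(0, 3, 1))
  lab <- rep(c("a", "b", "c"), each = n_per)
  m <- fit_lda(x, lab)
  orc <- oracle_pooled(x, lab)
  expect_equal(m$class_means, orc$means, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m$pooled_cov, orc$w, tolerance = 1e-9, ignore_attr = TRUE)
  # brute-force generalized eigenproblem: eigen(solve(W) B)
  grand <- colMeans(x)
  b <- matrix(0, 3, 3)
  for (cl in unique(lab)) {
    d <- orc$means[cl, ] - grand
    b <- b + n_per * d %o% d
  }
  b <- b / (nrow(x) - 3)
  eb <- eigen(solve(orc$w) %*% b)
  for (j in 1:2) {
    v_o <- Re(eb$vectors[, j])
    v_o <- v_o / sqrt(drop(t(v_o) %*% orc$w %*% v_o))
    if (v_o[which.max(abs(v_o))] < 0) v_o <- -v_o
    expect_equal(m$axes[, j], v_o, tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(m$axis_eigenvalues, Re(eb$values[1:2]), tolerance = 1e-8)
})

test_that("classification probabilities match full normal densities", {
  set.seed(3)
  sc <- two_class_scores(n_per = 8, m = 3, shift = 2, seed = 3)
  x3 <- rbind(sc$x, matrix(rnorm(8 * 3), ncol = 3) + 4)
  lab3 <- c(sc$labels, rep("c", 8))
  m <- fit_lda(x3, lab3)
  query <- matrix(rnorm(15), 5, 3)
  got <- classify_lda(m, query)
  orc <- oracle_pooled(x3, lab3)
  wi <- solve(orc$w)
  dens <- t(apply(query, 1, function(q) {
    sapply(rownames(orc$means), function(cl) {
      d <- q - orc$means[cl, ]
      (2 * pi)^(-1.5) * det(orc$w)^(-0.5) *
        exp(-0.5 * drop(t(d) %*% wi %*% d))
    })
  }))
  expect_equal(got$probabilities, dens / rowSums(dens),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(rowSums(got$probabilities)), rep(1, 5),
               tolerance = 1e-12)

  # class-order permutation equivariance: refit with reordered labels
  m_rev <- fit_lda(x3, factor(lab3, levels = c("c", "a", "b")))
  got_rev <- classify_lda(m_rev, query)
  expect_equal(got_rev$probabilities[, c("a", "b", "c")],
               got$probabilities, tolerance = 1e-12)

  # a query at a class mean wins under equal priors
  at_mean <- classify_lda(m, m$class_means["b", ])
  expect_equal(as.character(at_mean$predicted), "b")
})

test_that("leave-one-out cross-validation equals an explicit refit loop", {
  sc <- two_class_scores(n_per = 3, m = 2, shift = 3, seed = 4)
  got <- loocv_lda(sc$x, sc$labels)
  counts <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (i in 1:6) {
    orc <- oracle_pooled(sc$x[-i, ], sc$labels[-i])
    wi <- solve(orc$w)
    d2 <- sapply(rownames(orc$means), function(cl) {
      d <- sc$x[i, ] - orc$means[cl, ]
      drop(t(d) %*% wi %*% d)
    })
    pred <- names(which.min(d2))
    counts[sc$labels[i], pred] <- counts[sc$labels[i], pred] + 1L
  }
  expect_identical(got$counts, counts)
})

test_that("LOOCV is order-invariant, perfect at high separation, chance at none", {
  sep <- simulate_cluster_features(2, 15, 4, 8, seed = 5)
  conf <- loocv_lda(sep$features, sep$cluster)
  expect_equal(conf$overall_accuracy, 1)
  expect_equal(unname(conf$row_totals), c(15, 15))

  perm <- sample(nrow(sep$features))
  conf_p <- loocv_lda(sep$features[perm, ], sep$cluster[perm])
  expect_identical(conf_p$counts, conf$counts)

  # permuted labels: accuracy near chance (1/g), inside binomial 99% bounds
  set.seed(6)
  x0 <- matrix(rnorm(120 * 3), 120, 3)
  lab0 <- rep(c("a", "b"), 60)
  acc <- loocv_lda(x0, lab0)$overall_accuracy
  expect_lt(abs(acc - 0.5), 2.58 * sqrt(0.25 / 120) + 0.05)
})

test_that("Mahalanobis distances: closed forms and affine invariance", {
  set.seed(7)
  # identity pooled covariance, means differing by (3,4): distance 5
  z <- matrix(rnorm(60 * 2), 60, 2)
  z <- sweep(z, 2, colMeans(z))
  half <- z[1:30, ]; half2 <- z[31:60, ]
  half <- sweep(half, 2, colMeans(half)); half2 <- sweep(half2, 2, colMeans(half2))
  w_all <- (crossprod(half) + crossprod(half2)) / (60 - 2)
  tr <- solve(chol(w_all))
  x <- rbind(half %*% tr, sweep(half2 %*% tr, 2, -c(3, 4)))
  lab <- rep(c("a", "b"), each = 30)
  m <- fit_lda(x, lab)
  d <- mahalanobis_pairwise(m)
  expect_equal(d["a", "b"], 5, tolerance = 1e-9)
  expect_equal(diag(d), c(a = 0, b = 0))

  # invariance under an arbitrary invertible affine map of the scores
  a_map <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0, 0, -2, 0.7), 3, 3)
  sc <- two_class_scores(n_per = 12, m = 3, shift = 2, seed = 8)
  d1 <- mahalanobis_pairwise(fit_lda(sc$x, sc$labels))
  d2 <- mahalanobis_pairwise(fit_lda(sweep(sc$x %*% a_map, 2, -c(1, 2, 3)),
                                     sc$labels))
  expect_equal(d1, d2, tolerance = 1e-6)

  # identical means: zero distance
  xx <- rbind(sc$x[1:12, ], sc$x[1:12, ] + 1e-14)
  dd <- mahalanobis_pairwise(fit_lda(xx, rep(c("a", "b"), each = 12)))
  expect_lt(dd["a", "b"], 1e-4)
})

test_that("the implementation agrees with an established LDA reference", {
  library(MASS)
  set.seed(9)
  x <- rbind(matrix(rnorm(60), ncol = 3), matrix(rnorm(60), ncol = 3) + 1.5)
  lab <- rep(c("a", "b"), each = 20)
  mine <- fit_lda(x, lab)
  ref <- MASS::lda(x, grouping = lab, prior = c(0.5, 0.5))
  pm <- classify_lda(mine, x)
  pr <- predict(ref, x)
  expect_equal(pm$probabilities, pr$posterior, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(as.character(pm$predicted), as.character(pr$class))
  expect_equal(abs(mine$axes[, 1]), abs(ref$scaling[, 1]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("confusion matrices enforce bookkeeping invariants", {
  cm <- confusion_matrix(matrix(c(13L, 1L, 5L, 9L), 2, 2,
                                dimnames = list(c("AR", "US"), c("AR", "US"))))
  expect_equal(unname(cm$row_totals), c(18, 10))
  expect_equal(unname(cm$per_class_accuracy), c(13 / 18, 9 / 10))
  expect_error(confusion_matrix(matrix(-1, 2, 2,
                                       dimnames = list(1:2, 1:2))),
               "non-negative")
  expect_error(confusion_matrix(matrix(1, 2, 3)), "square")
})
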