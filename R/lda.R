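## Linear discriminant analysis in truncated principal-component space:
## group separation axes, posterior classification probabilities from the
## pooled within-group covariance, leave-one-out cross-validation, and
## pairwise Mahalanobis distances between group means.

#' Fit a linear discriminant model
#'
#' Computes class means, the unbiased pooled within-class covariance
#' (divisor n - g), and discriminant axes from the between- vs
#' within-group generalized eigenproblem. Axes are scaled to unit
#' within-group variance (a' W a = 1) and sign-fixed so each axis'
#' largest-magnitude loading is positive. Priors default to equal across
#' classes: class sample sizes here reflect sampling effort, not
#' prevalence.
#'
#' @param scores n x m feature matrix (typically truncated PC scores).
#' @param labels class label per row (>= 2 per class).
#' @param priors optional named numeric vector of prior probabilities
#'   (one per class, summing to 1), or `"proportional"` for priors equal
#'   to class frequencies.
#' @return An object of class `lda_model`: `classes`, `class_means`
#'   (g x m), `pooled_cov` (m x m), `axes` (m x r, r = min(g - 1, m)),
#'   `axis_eigenvalues`, `priors`, `counts`, `n`, `m`.
#' @export
fit_lda <- function(scores, labels, priors = NULL) {
  y <- as.matrix(scores)
  labels <- factor(labels)
  classes <- levels(labels)
  g <- length(classes)
  n <- nrow(y)
  m <- ncol(y)
  counts <- table(labels)
  if (g < 2L) stop("at least 2 classes are required")
  if (any(counts < 2L)) stop("every class needs at least 2 samples")
  if (m > n - g) {
    stop("dimensionality error: ", m, " features with n - g = ", n - g,
         " within-group degrees of freedom; use fewer components")
  }
  means <- matrix(NA_real_, g, m, dimnames = list(classes, colnames(y)))
  w <- matrix(0, m, m)
  for (ci in seq_len(g)) {
    yg <- y[labels == classes[ci], , drop = FALSE]
    means[ci, ] <- colMeans(yg)
    w <- w + crossprod(scale(yg, scale = FALSE))
  }
  w <- w / (n - g)
  ch <- tryCatch(chol(w), error = function(e) NULL)
  if (is.null(ch)) {
    stop("dimensionality error: singular pooled covariance; ",
         "use fewer components")
  }
  grand <- colMeans(y)
  b <- matrix(0, m, m)
  for (ci in seq_len(g)) {
    dlt <- means[ci, ] - grand
    b <- b + counts[ci] * tcrossprod(dlt)
  }
  b <- b / (n - g)
  ## generalized eigenproblem W^-1 B via the Cholesky factor of W
  s <- backsolve(ch, t(backsolve(ch, b, transpose = TRUE)), transpose = TRUE)
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)
  r <- min(g - 1L, m)
  axes <- backsolve(ch, es$vectors[, seq_len(r), drop = FALSE])
  for (j in seq_len(r)) {
    if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  }
  colnames(axes) <- paste0("LD", seq_len(r))

  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / g, g), classes)
  } else if (identical(priors, "proportional")) {
    priors <- stats::setNames(as.numeric(counts) / n, classes)
  } else {
    if (is.null(names(priors))) names(priors) <- classes
    priors <- priors[classes]
    if (anyNA(priors) || abs(sum(priors) - 1) > 1e-8) {
      stop("priors must cover every class and sum to 1")
    }
  }
  structure(
    list(classes = classes, class_means = means, pooled_cov = w,
         axes = axes, axis_eigenvalues = pmax(es$values[seq_len(r)], 0),
         priors = priors, counts = as.integer(counts), n = n, m = m),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat("lda_model:", length(x$classes), "classes in", x$m, "dimensions;",
      ncol(x$axes), "discriminant axes\n")
  invisible(x)
}

#' Classification probabilities under a discriminant model
#'
#' Computes the squared Mahalanobis distance of each row to every class
#' mean under the pooled covariance and converts to probabilities
#' proportional to `prior * exp(-D^2 / 2)`, rescaled to sum to one per
#' row (evaluated in log space for numerical stability). The predicted
#' class is the probability argmax; exact ties resolve to the earlier
#' class in `model$classes`.
#'
#' @param model an `lda_model`.
#' @param x m-vector or n x m matrix of feature rows.
#' @return A list with `probabilities` (n x g, rows sum to 1),
#'   `predicted` (factor), and `d2` (squared Mahalanobis distances).
#' @export
classify_lda <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$m) {
    stop("expected ", model$m, " features, got ", ncol(x))
  }
  g <- length(model$classes)
  ch <- chol(model$pooled_cov)
  d2 <- matrix(NA_real_, nrow(x), g,
               dimnames = list(rownames(x), model$classes))
  for (ci in seq_len(g)) {
    dlt <- sweep(x, 2L, model$class_means[ci, ])
    z <- backsolve(ch, t(dlt), transpose = TRUE)
    d2[, ci] <- colSums(z^2)
  }
  logp <- sweep(-d2 / 2, 2L, log(model$priors), `+`)
  logp <- logp - apply(logp, 1L, max)
  p <- exp(logp)
  p <- p / rowSums(p)
  pred_idx <- apply(p, 1L, which.max)
  list(probabilities = p,
       predicted = factor(model$classes[pred_idx], levels = model$classes),
       d2 = d2)
}

#' Build a confusion matrix object
#'
#' Rows are true classes, columns predicted classes. The constructor
#' enforces the bookkeeping invariants: non-negative integer counts and
#' row sums equal to the per-class sample totals.
#'
#' @param counts square matrix of counts with matching dimnames.
#' @return An object of class `confusion_matrix`: `labels`, `counts`,
#'   `per_class_accuracy`, `overall_accuracy`, `row_totals`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (is.null(rownames(counts)) || !identical(rownames(counts), colnames(counts))) {
    stop("row and column labels must match")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  rt <- rowSums(counts)
  structure(
    list(labels = rownames(counts), counts = counts,
         per_class_accuracy = ifelse(rt > 0, diag(counts) / rt, NA),
         overall_accuracy = sum(diag(counts)) / sum(counts),
         row_totals = rt),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = true, columns = predicted):\n")
  print(x$counts)
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' For each sample, refits the discriminant model on the remaining n - 1
#' samples and classifies the held-out one; accumulates the counts into
#' a [confusion_matrix()]. The result is invariant to sample order.
#'
#' @inheritParams fit_lda
#' @return A `confusion_matrix`.
#' @export
loocv_lda <- function(scores, labels, priors = NULL) {
  y <- as.matrix(scores)
  labels <- factor(labels)
  classes <- levels(labels)
  if (any(table(labels) < 3L)) {
    stop("every class needs at least 3 samples for leave-one-out")
  }
  n <- nrow(y)
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (i in seq_len(n)) {
    fit <- fit_lda(y[-i, , drop = FALSE], labels[-i], priors = priors)
    pred <- classify_lda(fit, y[i, ])$predicted
    counts[as.character(labels[i]), as.character(pred)] <-
      counts[as.character(labels[i]), as.character(pred)] + 1L
  }
  confusion_matrix(counts)
}

#' Pairwise Mahalanobis distances between class means
#'
#' D(a, b) = sqrt((mu_a - mu_b)' W^-1 (mu_a - mu_b)) with W the pooled
#' within-class covariance of the fitted model. Distances are invariant
#' under any invertible affine transformation of the feature space.
#'
#' @param model an `lda_model`.
#' @return Symmetric non-negative matrix with zero diagonal, labeled by
#'   class.
#' @export
mahalanobis_pairwise <- function(model) {
  g <- length(model$classes)
  ch <- chol(model$pooled_cov)
  d <- matrix(0, g, g, dimnames = list(model$classes, model$classes))
  for (a in seq_len(g - 1L)) {
    for (b in seq((a + 1L), g)) {
      dlt <- model$class_means[a, ] - model$class_means[b, ]
      z <- backsolve(ch, dlt, transpose = TRUE)
      d[a, b] <- d[b, a] <- sqrt(sum(z^2))
    }
  }
  d
}
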