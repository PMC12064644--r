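## Generalized Procrustes analysis.
##
## Partial Procrustes superimposition: every configuration is centered,
## scaled to unit centroid size, and rotated (reflection-free) onto an
## iteratively refined consensus. With tangent projection on (the default)
## the aligned coordinates of 2-D data lose exactly four degrees of
## freedom (two translations, one rotation, one scale), so the covariance
## of k-landmark shapes has exactly 2k - 4 informative dimensions.

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; the size measure removed by Procrustes scaling.
#'
#' @param config a k x 2 coordinate matrix or a length-2k vector ordered
#'   `(x1, y1, ...)`.
#' @return A positive scalar in the configuration's original units.
#' @export
centroid_size <- function(config) {
  m <- if (is.matrix(config)) config else config_matrix(config)
  if (nrow(m) < 3L) stop("at least 3 landmarks are required")
  ctr <- sweep(m, 2L, colMeans(m))
  cs <- sqrt(sum(ctr^2))
  if (cs < 1e-12) stop("degenerate configuration: all landmarks coincide")
  cs
}

## Center a k x 2 configuration and scale it to unit centroid size.
center_scale <- function(m) {
  ctr <- sweep(m, 2L, colMeans(m))
  cs <- sqrt(sum(ctr^2))
  if (cs < 1e-12) stop("degenerate configuration: all landmarks coincide")
  ctr / cs
}

## Optimal reflection-free (det = +1) rotation of X onto target C; both
## k x 2 and centered. Ties among singular values are resolved by the
## canonical SVD convention with the determinant correction.
rotate_onto <- function(x, target) {
  h <- crossprod(x, target)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  r <- s$u %*% diag(c(1, d)) %*% t(s$v)
  x %*% r
}

## Orthogonal projection of aligned rows onto the tangent space at the
## unit consensus c: x -> x - (x . c - 1) c. Removes the scale direction;
## translation and rotation directions are already annihilated by
## centering and optimal rotation.
tangent_project <- function(aligned, consensus) {
  along <- drop(aligned %*% consensus) - 1
  aligned - outer(along, consensus)
}

#' Generalized Procrustes alignment
#'
#' Iteratively centers, unit-scales, and rotates all configurations onto
#' an evolving consensus (partial Procrustes: no further scaling during
#' rotation). The initial consensus is the first configuration after
#' centering and scaling; iteration stops when the consensus moves less
#' than `tol` in Procrustes distance or after `max_iter` sweeps, and a
#' final rotation pass superimposes every configuration on the converged
#' consensus. With `project = TRUE` the aligned coordinates are then
#' orthogonally projected onto the tangent space at the consensus.
#'
#' @param x a [landmark_dataset()] or an n x 2k coordinate matrix.
#' @param tol convergence tolerance on consensus movement.
#' @param max_iter maximum number of sweeps; non-convergence is recorded
#'   in the `converged` flag, not raised as an error.
#' @param project apply tangent-space projection (default `TRUE`).
#' @return An object of class `gpa_fit`: `aligned` (n x 2k), `consensus`
#'   (2k, centered, unit centroid size), `centroid_sizes` (original
#'   units), `iterations`, `converged`, `projected`, `ss_trace` (sum of
#'   squared distances to the consensus per sweep), `k`, and the input
#'   metadata in `meta` when available.
#' @export
align_gpa <- function(x, tol = 1e-8, max_iter = 100L, project = TRUE) {
  meta <- NULL
  if (inherits(x, "landmark_dataset")) {
    meta <- x$meta
    coords <- x$coords
  } else {
    coords <- as.matrix(x)
  }
  n <- nrow(coords)
  if (n < 2L) stop("at least 2 configurations are required")
  k <- ncol(coords) / 2L
  mats <- lapply(seq_len(n), function(i) config_matrix(coords[i, ]))
  sizes <- vapply(mats, centroid_size, numeric(1L))
  mats <- lapply(mats, center_scale)

  consensus <- mats[[1L]]
  iterations <- 0L
  converged <- FALSE
  ss_trace <- numeric(0)
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    mats <- lapply(mats, rotate_onto, target = consensus)
    new_cons <- Reduce(`+`, mats) / n
    new_cons <- center_scale(new_cons)
    ss_trace[iterations] <- sum(vapply(mats, function(m) {
      sum((m - new_cons)^2)
    }, numeric(1L)))
    moved <- sqrt(sum((rotate_onto(new_cons, consensus) - consensus)^2))
    consensus <- new_cons
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("GPA did not converge in ", max_iter, " iterations")
  }
  mats <- lapply(mats, rotate_onto, target = consensus)

  aligned <- t(vapply(mats, config_vector, numeric(2L * k)))
  cons_vec <- config_vector(consensus)
  if (project) aligned <- tangent_project(aligned, cons_vec)
  colnames(aligned) <- coord_colnames(k)
  rownames(aligned) <- rownames(coords)
  structure(
    list(aligned = aligned, consensus = cons_vec, centroid_sizes = sizes,
         iterations = iterations, converged = converged, projected = project,
         ss_trace = ss_trace, k = k, meta = meta),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("gpa_fit:", nrow(x$aligned), "configurations,", x$k, "landmarks;",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)",
      if (x$projected) "- tangent projected" else "", "\n")
  invisible(x)
}

#' Procrustes distance between two aligned shapes
#'
#' Euclidean norm of the difference after centering both shapes and
#' optimally rotating (reflection-free) `b` onto `a`.
#'
#' @param a,b length-2k shape vectors.
#' @return A non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (length(a) != length(b)) stop("shape vectors must have equal length")
  ma <- config_matrix(a)
  mb <- config_matrix(b)
  ma <- sweep(ma, 2L, colMeans(ma))
  mb <- sweep(mb, 2L, colMeans(mb))
  sqrt(sum((rotate_onto(mb, ma) - ma)^2))
}

#' Align a single configuration onto a fixed consensus
#'
#' Centers, unit-scales, and rotates one configuration onto the consensus
#' of a fitted alignment without refitting the consensus; used to place
#' unknown specimens into an existing shape space before classification.
#'
#' @param config a k x 2 matrix or length-2k vector.
#' @param consensus length-2k consensus from a `gpa_fit` (centered, unit
#'   centroid size).
#' @param project apply the same tangent projection as the fit that
#'   produced `consensus` (default `TRUE`).
#' @return A length-2k aligned shape vector.
#' @export
align_to_consensus <- function(config, consensus, project = TRUE) {
  m <- if (is.matrix(config)) config else config_matrix(config)
  if (2L * nrow(m) != length(consensus)) {
    stop("configuration has ", nrow(m), " landmarks but consensus expects ",
         length(consensus) / 2L)
  }
  m <- center_scale(m)
  aligned <- config_vector(rotate_onto(m, config_matrix(consensus)))
  if (project) {
    aligned <- drop(tangent_project(matrix(aligned, 1L), consensus))
  }
  aligned
}
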