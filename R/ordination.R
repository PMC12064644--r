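## Ordination: PCA of aligned coordinates and classical scaling (PCoA)
## of distance matrices. For 2-D Procrustes-projected data the last four
## PCA eigenvalues are exactly zero, so retaining 2k - 4 components
## (34 for 19 landmarks) loses nothing.

#' Principal component analysis of shape features
#'
#' Eigendecomposition of the covariance of the centered feature rows.
#' The sign of each eigenvector is fixed so its largest-magnitude entry
#' is positive, making scores reproducible across platforms.
#'
#' @param features n x d numeric matrix (e.g. aligned coordinates or
#'   sample mean shapes).
#' @param m_retain number of components whose scores are retained;
#'   must not exceed `min(n - 1, d)`. Defaults to that maximum.
#' @return An object of class `shape_pca`: `mean` (d), `eigenvectors`
#'   (d x d, orthonormal columns), `eigenvalues` (d, descending,
#'   non-negative), `scores` (n x m_retain), `m_retained`.
#' @export
shape_pca <- function(features, m_retain = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  d <- ncol(features)
  if (n < 2L) stop("at least 2 rows are required")
  m_max <- min(n - 1L, d)
  if (is.null(m_retain)) m_retain <- m_max
  if (m_retain < 1L || m_retain > m_max) {
    stop("m_retain must be in [1, ", m_max, "], got ", m_retain)
  }
  mu <- colMeans(features)
  xc <- sweep(features, 2L, mu)
  cv <- crossprod(xc) / (n - 1L)
  ev <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  for (j in seq_len(d)) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- xc %*% vecs[, seq_len(m_retain), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(m_retain))
  rownames(scores) <- rownames(features)
  structure(
    list(mean = mu, eigenvectors = vecs, eigenvalues = vals,
         scores = scores, m_retained = m_retain),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  kept <- sum(x$eigenvalues[seq_len(x$m_retained)])
  cat("shape_pca:", length(x$eigenvalues), "components,",
      x$m_retained, "retained",
      sprintf("(%.1f%% of variance)\n", if (tot > 0) 100 * kept / tot else 0))
  invisible(x)
}

#' Project new feature rows onto fitted principal components
#'
#' @param pca a `shape_pca`.
#' @param features matrix or vector of rows in the original feature space.
#' @param m number of components (default: the fit's `m_retained`).
#' @return Score matrix.
#' @export
pca_transform <- function(pca, features, m = pca$m_retained) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  xc <- sweep(as.matrix(features), 2L, pca$mean)
  xc %*% pca$eigenvectors[, seq_len(m), drop = FALSE]
}

#' Number of components needed to explain a variance fraction
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @param frac target cumulative variance fraction in (0, 1].
#' @return The smallest m with cumulative fraction >= `frac`.
#' @export
variance_threshold_components <- function(eigenvalues, frac) {
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be non-negative")
  eigenvalues <- pmax(eigenvalues, 0)
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("degenerate spectrum: all eigenvalues are zero")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  cumfrac <- cumsum(eigenvalues) / tot
  which(cumfrac >= frac - 1e-12)[1L]
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a symmetric distance matrix into coordinates via
#' [stats::cmdscale()]: double-center -D^2/2, eigendecompose, and keep
#' the axes with positive eigenvalues.
#'
#' @param dist_matrix square symmetric non-negative matrix with zero
#'   diagonal.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are dropped.
#' @return A list with `coordinates` (n x m, columns `PCo1`, ...) and
#'   `eigenvalues` (all n - 1 values, descending).
#' @export
shape_pcoa <- function(dist_matrix, tol = 1e-9) {
  d <- as.matrix(dist_matrix)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  n <- nrow(d)
  ## we request all n - 1 axes and drop non-positive eigenvalues ourselves,
  ## so cmdscale's warning about them is expected
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig[seq_len(n - 1L)]
  keep <- which(eig > tol * max(eig, 0))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(keep))
  rownames(coords) <- rownames(d)
  list(coordinates = coords, eigenvalues = eig)
}
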