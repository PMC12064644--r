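## Gaussian mixture model-based clustering.
##
## EM over six canonical covariance structures (the spherical / diagonal
## / full x equal / varying grid), deterministically initialized from an
## agglomerative Ward partition so that a fixed (seed, data) pair gives a
## bit-identical model. Model selection maximizes
## BIC = 2 loglik - npar log(n) over a (K, family) grid.

#' The six supported covariance families
#' @return Character vector of family codes.
#' @export
gmm_families <- function() {
  c("spherical-equal", "spherical-varying",
    "diagonal-equal", "diagonal-varying",
    "full-equal", "full-varying")
}

## free covariance parameters per family
gmm_cov_params <- function(family, k, m) {
  switch(family,
    "spherical-equal"   = 1,
    "spherical-varying" = k,
    "diagonal-equal"    = m,
    "diagonal-varying"  = k * m,
    "full-equal"        = m * (m + 1) / 2,
    "full-varying"      = k * m * (m + 1) / 2,
    stop("unknown family: ", family)
  )
}

logsumexp_rows <- function(a) {
  mx <- apply(a, 1L, max)
  mx + log(rowSums(exp(a - mx)))
}

## multivariate normal log density for all rows given a Cholesky factor
mvn_logdens <- function(x, mu, ch) {
  m <- ncol(x)
  z <- backsolve(ch, t(sweep(x, 2L, mu)), transpose = TRUE)
  -0.5 * m * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

## Cholesky with a diagonal regularization floor applied on failure.
chol_reg <- function(sigma, floor_val) {
  regularized <- FALSE
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  tries <- 0L
  while (is.null(ch) && tries < 6L) {
    tries <- tries + 1L
    regularized <- TRUE
    sigma <- sigma + diag(floor_val * 10^(tries - 1L), nrow(sigma))
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
  }
  if (is.null(ch)) stop("covariance could not be regularized")
  list(chol = ch, regularized = regularized)
}

gmm_mstep <- function(x, z, family, floor_val) {
  n <- nrow(x)
  m <- ncol(x)
  k <- ncol(z)
  nk <- colSums(z)
  if (any(nk < 1e-8)) stop("empty-component")
  if (family == "full-varying" && any(nk < m + 1)) {
    stop("component too small (", signif(min(nk), 3),
         " effective points) to estimate a full per-component covariance")
  }
  if (family %in% c("diagonal-varying", "spherical-varying") && any(nk < 2)) {
    stop("component too small to estimate a per-component covariance")
  }
  w <- nk / n
  mu <- crossprod(z, x) / nk
  scat <- vector("list", k)
  for (ci in seq_len(k)) {
    xc <- sweep(x, 2L, mu[ci, ])
    scat[[ci]] <- crossprod(xc * z[, ci], xc)
  }
  sig <- vector("list", k)
  if (family == "spherical-equal") {
    s2 <- sum(vapply(scat, function(s) sum(diag(s)), numeric(1L))) / (m * n)
    for (ci in seq_len(k)) sig[[ci]] <- diag(s2, m)
  } else if (family == "spherical-varying") {
    for (ci in seq_len(k)) sig[[ci]] <- diag(sum(diag(scat[[ci]])) / (m * nk[ci]), m)
  } else if (family == "diagonal-equal") {
    dd <- Reduce(`+`, lapply(scat, diag)) / n
    for (ci in seq_len(k)) sig[[ci]] <- diag(dd, m)
  } else if (family == "diagonal-varying") {
    for (ci in seq_len(k)) sig[[ci]] <- diag(diag(scat[[ci]]) / nk[ci], m)
  } else if (family == "full-equal") {
    ss <- Reduce(`+`, scat) / n
    for (ci in seq_len(k)) sig[[ci]] <- ss
  } else if (family == "full-varying") {
    for (ci in seq_len(k)) sig[[ci]] <- scat[[ci]] / nk[ci]
  } else {
    stop("unknown family: ", family)
  }
  regularized <- FALSE
  chols <- vector("list", k)
  for (ci in seq_len(k)) {
    cr <- chol_reg(sig[[ci]], floor_val)
    chols[[ci]] <- cr$chol
    if (cr$regularized) {
      regularized <- TRUE
      sig[[ci]] <- crossprod(cr$chol)
    }
  }
  list(weights = w, means = mu, covariances = sig, chols = chols,
       regularized = regularized)
}

gmm_estep <- function(x, par) {
  k <- length(par$chols)
  lg <- matrix(NA_real_, nrow(x), k)
  for (ci in seq_len(k)) {
    lg[, ci] <- log(par$weights[ci]) + mvn_logdens(x, par$means[ci, ], par$chols[[ci]])
  }
  lse <- logsumexp_rows(lg)
  list(z = exp(lg - lse), loglik = sum(lse))
}

#' Fit a Gaussian mixture model by EM
#'
#' Initializes responsibilities from the K-group agglomerative Ward
#' partition of the features (deterministic), then alternates M and E
#' steps until the log-likelihood gain drops below `tol`. An empty
#' component triggers one restart with perturbed responsibilities, then
#' an error. A singular component covariance receives a diagonal
#' regularization floor of `1e-8 *` mean feature variance and the fit is
#' flagged `regularized`.
#'
#' @param features n x m numeric matrix.
#' @param K number of components (n > K).
#' @param family covariance structure, one of [gmm_families()].
#' @param seed integer seed (used only for the perturbed restart).
#' @param tol convergence tolerance on log-likelihood gain.
#' @param max_iter maximum EM iterations.
#' @return An object of class `gmm_fit`: `K`, `family`, `weights`,
#'   `means` (K x m), `covariances` (list of m x m), `loglik`,
#'   `loglik_trace`, `n_params`, `bic` (= 2 loglik - npar log n),
#'   `responsibilities` (n x K, rows sum to 1), `converged`,
#'   `regularized`, `seed`.
#' @export
fit_gmm <- function(features, K, family = "full-equal", seed = NULL,
                    tol = 1e-8, max_iter = 500L) {
  x <- as.matrix(features)
  n <- nrow(x)
  m <- ncol(x)
  if (n <= K) stop("need more observations than components")
  if (!family %in% gmm_families()) {
    stop("unknown family '", family, "'; see gmm_families()")
  }
  floor_val <- 1e-8 * mean(apply(x, 2L, stats::var))
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- 1e-12

  init_z <- function() {
    hard <- if (K == 1L) rep(1L, n) else {
      stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = K)
    }
    z <- matrix(0, n, K)
    z[cbind(seq_len(n), hard)] <- 1
    z
  }
  run_em <- function(z) {
    trace <- numeric(0)
    loglik <- -Inf
    converged <- FALSE
    regularized <- FALSE
    par <- NULL
    for (it in seq_len(max_iter)) {
      par <- gmm_mstep(x, z, family, floor_val)
      regularized <- regularized || par$regularized
      es <- gmm_estep(x, par)
      z <- es$z
      trace <- c(trace, es$loglik)
      if (is.finite(loglik) && es$loglik - loglik < tol) {
        loglik <- es$loglik
        converged <- TRUE
        break
      }
      loglik <- es$loglik
    }
    list(par = par, z = z, loglik = loglik, trace = trace,
         converged = converged, regularized = regularized)
  }

  res <- tryCatch(run_em(init_z()), error = function(e) e)
  if (inherits(res, "error")) {
    if (!grepl("empty-component", conditionMessage(res))) stop(res)
    res <- with_seed(if (is.null(seed)) 0L else seed, {
      z <- init_z()
      z <- 0.9 * z + 0.1 * matrix(stats::runif(n * K), n, K)
      z <- z / rowSums(z)
      tryCatch(run_em(z), error = function(e) e)
    })
    if (inherits(res, "error")) {
      stop("EM failed after perturbed restart: ", conditionMessage(res))
    }
  }
  npar <- (K - 1) + K * m + gmm_cov_params(family, K, m)
  structure(
    list(K = K, family = family,
         weights = res$par$weights, means = res$par$means,
         covariances = res$par$covariances,
         loglik = res$loglik, loglik_trace = res$trace,
         n_params = npar, bic = 2 * res$loglik - npar * log(n),
         responsibilities = res$z,
         converged = res$converged, regularized = res$regularized,
         seed = seed),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("gmm_fit: K =", x$K, "(", x$family, "), loglik =",
      signif(x$loglik, 6), ", BIC =", signif(x$bic, 6),
      if (x$regularized) "[regularized]" else "", "\n")
  invisible(x)
}

#' Select a mixture model by BIC over a (K, family) grid
#'
#' Fits every combination of component count and covariance family and
#' returns the maximum-BIC model; the full BIC table (including failed
#' fits and their causes) is attached as `bic_table`.
#'
#' @param features n x m numeric matrix.
#' @param K_range candidate component counts (default 1:9).
#' @param families candidate covariance families (default all six).
#' @param seed integer seed, passed to each fit.
#' @param ... further arguments to [fit_gmm()].
#' @return The best `gmm_fit`, with a `bic_table` data frame attached.
#' @export
select_model_bic <- function(features, K_range = 1:9,
                             families = gmm_families(), seed = NULL, ...) {
  if (length(K_range) == 0L) stop("K_range must be non-empty")
  fits <- list()
  rows <- list()
  for (K in K_range) {
    for (fam in families) {
      key <- paste(K, fam, sep = "/")
      fit <- tryCatch(fit_gmm(features, K, fam, seed = seed, ...),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[key]] <- data.frame(K = K, family = fam, loglik = NA_real_,
                                  n_params = NA_real_, bic = NA_real_,
                                  converged = NA,
                                  note = conditionMessage(fit),
                                  stringsAsFactors = FALSE)
      } else {
        fits[[key]] <- fit
        rows[[key]] <- data.frame(K = K, family = fam, loglik = fit$loglik,
                                  n_params = fit$n_params, bic = fit$bic,
                                  converged = fit$converged,
                                  note = if (fit$regularized) "regularized" else "",
                                  stringsAsFactors = FALSE)
      }
    }
  }
  bic_table <- do.call(rbind, rows)
  rownames(bic_table) <- NULL
  if (length(fits) == 0L) {
    stop("all mixture fits failed:\n",
         paste(bic_table$note, collapse = "\n"))
  }
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "bic"))]]
  best$bic_table <- bic_table
  best
}

#' Cross-tabulate mixture clusters against known labels
#'
#' Hard-assigns each sample to its maximum-responsibility cluster and
#' tabulates against known population labels.
#'
#' @param model a `gmm_fit`.
#' @param labels one known label per sample.
#' @return A list with `counts` (cluster x label), `cluster_prop`
#'   (rows sum to 1) and `label_prop` (columns sum to 1).
#' @export
cluster_composition <- function(model, labels) {
  z <- model$responsibilities
  if (length(labels) != nrow(z)) {
    stop("expected ", nrow(z), " labels, got ", length(labels))
  }
  hard <- max.col(z, ties.method = "first")
  counts <- table(cluster = factor(hard, levels = seq_len(model$K)),
                  label = labels)
  counts <- unclass(counts)
  list(counts = counts,
       cluster_prop = counts / pmax(rowSums(counts), 1L),
       label_prop = sweep(counts, 2L, pmax(colSums(counts), 1L), `/`))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar.
#' @export
cluster_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
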