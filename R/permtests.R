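## Permutation-tested multivariate linear models: shape-on-geography
## regression with residual randomization (RRPP) and MANOVA with
## permutation-tested pairwise comparisons.

## Run `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

hat_matrix <- function(x) {
  q <- qr.Q(qr(x))
  tcrossprod(q)
}

#' Multivariate shape regression with residual randomization (RRPP)
#'
#' Sequential (type-I) decomposition of the total sum of squared
#' coordinates over the covariate terms, in the order given. For each
#' term, F = (SS_term / df_term) / (SS_resid / df_resid). Significance is
#' assessed by residual randomization under the reduced model: the
#' residuals of the model containing all preceding terms are permuted,
#' added back to the reduced-model fit, and F recomputed;
#' p = (number of permuted F >= observed + 1) / (n_perm + 1).
#'
#' F statistics are invariant to affine rescaling of covariates (degrees
#' vs radians of latitude give identical results).
#'
#' @param shapes n x d response matrix (aligned coordinates or sample
#'   mean shapes).
#' @param covariates data frame (or matrix) of numeric covariates, one
#'   column per term, tested in column order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed making the permutation p-values reproducible.
#' @return An object of class `rrpp_fit`: data frame `aov_table` with
#'   `term`, `df`, `SS`, `MS`, `F`, `p_perm`, plus residual and total
#'   rows; and fields `n_perm`, `seed`.
#' @export
regress_shape_rrpp <- function(shapes, covariates, n_perm = 999L, seed = NULL) {
  y <- as.matrix(shapes)
  cov_df <- as.data.frame(covariates)
  n <- nrow(y)
  t_terms <- ncol(cov_df)
  if (nrow(cov_df) != n) stop("covariates must have one row per shape")
  if (n <= t_terms + 1L) stop("need n > number of terms + 1")
  for (nm in names(cov_df)) {
    v <- cov_df[[nm]]
    if (!is.numeric(v)) stop("covariate '", nm, "' must be numeric")
    if (stats::sd(v) < 1e-12) stop("covariate '", nm, "' is constant")
  }
  terms <- names(cov_df)

  ## nested hat matrices: intercept, +term1, +term1+term2, ...
  x <- matrix(1, n, 1L)
  hats <- vector("list", t_terms + 1L)
  hats[[1L]] <- hat_matrix(x)
  for (j in seq_len(t_terms)) {
    x <- cbind(x, cov_df[[j]])
    hats[[j + 1L]] <- hat_matrix(x)
  }
  h_full <- hats[[t_terms + 1L]]
  df_resid <- n - t_terms - 1L

  term_ss <- function(yy) {
    res_full <- yy - h_full %*% yy
    ss_res <- sum(res_full^2)
    ss <- vapply(seq_len(t_terms), function(j) {
      sum(((hats[[j + 1L]] - hats[[j]]) %*% yy)^2)
    }, numeric(1L))
    list(ss = ss, ss_res = ss_res)
  }

  obs <- term_ss(y)
  f_obs <- (obs$ss / 1) / (obs$ss_res / df_resid)

  exceed <- integer(t_terms)
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    for (j in seq_len(t_terms)) {
      h_red <- hats[[j]]
      fit_red <- h_red %*% y
      res_red <- y - fit_red
      for (p in perms) {
        y_star <- fit_red + res_red[p, , drop = FALSE]
        st <- term_ss(y_star)
        f_star <- (st$ss[j] / 1) / (st$ss_res / df_resid)
        if (f_star >= f_obs[j]) exceed[j] <- exceed[j] + 1L
      }
    }
  })
  p_perm <- (exceed + 1L) / (n_perm + 1L)

  ss_tot <- sum(scale(y, scale = FALSE)^2)
  aov_table <- data.frame(
    term = c(terms, "Residuals", "Total"),
    df = c(rep(1L, t_terms), df_resid, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_tot),
    MS = c(obs$ss, obs$ss_res / df_resid, NA),
    F = c(f_obs, NA, NA),
    p_perm = c(p_perm, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(aov_table = aov_table, n_perm = n_perm, seed = seed),
            class = "rrpp_fit")
}

#' @export
print.rrpp_fit <- function(x, ...) {
  cat("Multivariate shape regression (RRPP,", x$n_perm, "permutations)\n")
  print(x$aov_table, row.names = FALSE, digits = 4)
  invisible(x)
}

## Pillai trace for a grouped multivariate sample: tr(H (H + E)^-1),
## with H the between-group and E the within-group SSCP.
pillai_trace <- function(y, labels) {
  yc <- scale(y, scale = FALSE)
  tot <- crossprod(yc)
  e <- matrix(0, ncol(y), ncol(y))
  for (g in unique(labels)) {
    yg <- y[labels == g, , drop = FALSE]
    e <- e + crossprod(scale(yg, scale = FALSE))
  }
  h <- tot - e
  sum(diag(h %*% solve(tot)))
}

#' MANOVA across populations with permutation-tested pairwise comparisons
#'
#' The overall test is the Pillai trace with its standard F
#' approximation (via [stats::manova()]). Each pair of groups is then
#' compared by recomputing the two-group Pillai statistic under random
#' label permutations, p = (b + 1) / (n_perm + 1); with `exact = TRUE`
#' all distinct label assignments are enumerated instead (feasible for
#' small groups only). The pairwise matrix is returned unadjusted by
#' default; `adjust` passes any [stats::p.adjust()] method.
#'
#' @param scores n x m score matrix (m < n - number of groups).
#' @param labels group label per row.
#' @param n_perm permutations per pairwise test (default 9999).
#' @param seed integer seed for reproducible permutations.
#' @param exact enumerate all label assignments per pair instead of
#'   sampling.
#' @param adjust p-adjustment method for the pairwise matrix
#'   (default `"none"`).
#' @return An object of class `manova_result`: `statistic_name`
#'   (`"Pillai"`), `statistic`, `F_approx`, `df`, `p` (parametric overall
#'   p), `pairwise_p` (symmetric matrix, `NA` diagonal), `n_perm`,
#'   `seed`.
#' @export
manova_populations <- function(scores, labels, n_perm = 9999L, seed = NULL,
                               exact = FALSE, adjust = "none") {
  y <- as.matrix(scores)
  labels <- factor(labels)
  groups <- levels(labels)
  g <- length(groups)
  n <- nrow(y)
  m <- ncol(y)
  if (g < 2L) stop("at least 2 groups are required")
  if (any(table(labels) < 2L)) stop("every group needs at least 2 samples")
  if (m >= n - g) {
    stop("dimensionality error: ", m, " components with ", n, " samples in ",
         g, " groups leaves a singular within-group covariance; ",
         "use fewer components")
  }
  fit <- stats::manova(y ~ labels)
  sm <- summary(fit, test = "Pillai")$stats
  statistic <- sm[1L, "Pillai"]
  f_approx <- sm[1L, "approx F"]
  df <- c(sm[1L, "num Df"], sm[1L, "den Df"])
  p_overall <- sm[1L, "Pr(>F)"]

  pairwise <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  with_seed(seed, {
    for (a in seq_len(g - 1L)) {
      for (b in seq((a + 1L), g)) {
        sel <- labels %in% groups[c(a, b)]
        ys <- y[sel, , drop = FALSE]
        ls <- droplevels(labels[sel])
        if (m > nrow(ys) - 3L) {
          stop("dimensionality error: pair ", groups[a], "/", groups[b],
               " has ", nrow(ys), " samples for ", m,
               " components; use fewer components")
        }
        obs <- pillai_trace(ys, ls)
        ns <- nrow(ys)
        n1 <- sum(ls == levels(ls)[1L])
        if (exact) {
          combos <- utils::combn(ns, n1)
          stats_all <- apply(combos, 2L, function(idx) {
            ll <- rep(levels(ls)[2L], ns)
            ll[idx] <- levels(ls)[1L]
            pillai_trace(ys, factor(ll))
          })
          p <- mean(stats_all >= obs - 1e-12)
        } else {
          bcount <- 0L
          for (i in seq_len(n_perm)) {
            if (pillai_trace(ys, sample(ls)) >= obs - 1e-12) {
              bcount <- bcount + 1L
            }
          }
          p <- (bcount + 1L) / (n_perm + 1L)
        }
        pairwise[a, b] <- pairwise[b, a] <- p
      }
    }
  })
  if (adjust != "none") {
    up <- upper.tri(pairwise)
    pairwise[up] <- stats::p.adjust(pairwise[up], method = adjust)
    pairwise[lower.tri(pairwise)] <- t(pairwise)[lower.tri(pairwise)]
  }
  structure(
    list(statistic_name = "Pillai", statistic = statistic,
         F_approx = f_approx, df = df, p = p_overall,
         pairwise_p = pairwise, n_perm = n_perm, seed = seed),
    class = "manova_result"
  )
}

#' @export
print.manova_result <- function(x, ...) {
  cat("MANOVA (", x$statistic_name, " = ", signif(x$statistic, 4),
      "): approx F = ", signif(x$F_approx, 4),
      ", p = ", format.pval(x$p), "\n", sep = "")
  cat("pairwise permutation p-values (", x$n_perm, " permutations):\n", sep = "")
  print(round(x$pairwise_p, 4))
  invisible(x)
}
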