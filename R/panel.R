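## Reference lineage panels: a consensus shape, a truncated PC basis and
## a discriminant model over evolutionary-lineage labels (A, C, M, O),
## serializable to a portable text file so panels can be shared without
## redistributing the raw reference coordinates.

#' Build a reference lineage panel
#'
#' Fits a PCA basis and a linear discriminant model over lineage labels
#' on an aligned reference dataset (typically colony mean shapes). The
#' panel stores everything needed to classify unknown wings: the
#' consensus, the component basis, lineage means, pooled covariance and
#' priors.
#'
#' @param fit a `gpa_fit` over the reference configurations, or an
#'   aligned n x 2k matrix together with `consensus`.
#' @param labels lineage label per aligned row (>= 2 lineages, each with
#'   >= 2 rows).
#' @param m_retain number of principal components kept for the
#'   discriminant space; default `min(2k - 4, n - g - 1)`.
#' @param consensus length-2k consensus (required when `fit` is a bare
#'   matrix).
#' @param priors as in [fit_lda()].
#' @return An object of class `lineage_panel`.
#' @export
build_panel <- function(fit, labels, m_retain = NULL, consensus = NULL,
                        priors = NULL) {
  if (inherits(fit, "gpa_fit")) {
    aligned <- fit$aligned
    consensus <- fit$consensus
    projected <- fit$projected
  } else {
    aligned <- as.matrix(fit)
    if (is.null(consensus)) stop("consensus required with a bare matrix")
    projected <- TRUE
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("at least 2 lineages are required")
  if (any(table(labels) < 2L)) stop("every lineage needs at least 2 rows")
  n <- nrow(aligned)
  g <- nlevels(labels)
  k <- ncol(aligned) / 2L
  if (is.null(m_retain)) m_retain <- min(2L * k - 4L, n - g - 1L)
  pca <- shape_pca(aligned, m_retain = m_retain)
  model <- fit_lda(pca$scores, labels, priors = priors)
  structure(
    list(consensus = consensus, center = pca$mean,
         basis = pca$eigenvectors[, seq_len(m_retain), drop = FALSE],
         m_retain = m_retain, projected = projected, k = k,
         model = model, classes = model$classes),
    class = "lineage_panel"
  )
}

#' @export
print.lineage_panel <- function(x, ...) {
  cat("lineage_panel:", length(x$classes), "lineages (",
      paste(x$classes, collapse = ", "), "),", x$k, "landmarks,",
      x$m_retain, "components\n")
  invisible(x)
}

#' Assign unknown samples to reference lineages
#'
#' Aligns each unknown configuration onto the panel consensus (no
#' consensus refit), projects it into the panel's component basis, and
#' computes rescaled classification probabilities (softmax of
#' `-D^2/2` under the pooled lineage covariance; rescaled so each row
#' sums to one). Assignment is invariant to rigid motion and scaling of
#' the unknown.
#'
#' @param panel a `lineage_panel`.
#' @param unknown one configuration (k x 2 matrix or 2k vector), an
#'   n x 2k matrix of shape rows, or a `sample_table` of mean shapes.
#' @param already_aligned set `TRUE` when `unknown` rows are already in
#'   the panel's shape space (skips re-alignment).
#' @return A data frame with `sample_id`, one probability column per
#'   lineage, and `predicted`.
#' @export
assign_lineages <- function(panel, unknown, already_aligned = FALSE) {
  if (inherits(unknown, "sample_table")) {
    ids <- unknown$meta$sample_id
    rows <- unknown$mean_shapes
  } else if (is.matrix(unknown) && ncol(unknown) == 2L) {
    ids <- "unknown_1"
    rows <- matrix(config_vector(unknown), 1L)
  } else if (is.null(dim(unknown))) {
    ids <- "unknown_1"
    rows <- matrix(unknown, 1L)
  } else {
    rows <- as.matrix(unknown)
    ids <- rownames(rows)
    if (is.null(ids)) ids <- paste0("unknown_", seq_len(nrow(rows)))
  }
  if (ncol(rows) != 2L * panel$k) {
    stop("unknown has ", ncol(rows) / 2L, " landmarks but the panel expects ",
         panel$k)
  }
  if (!already_aligned) {
    rows <- t(apply(rows, 1L, align_to_consensus,
                    consensus = panel$consensus, project = panel$projected))
  }
  scores <- sweep(rows, 2L, panel$center) %*% panel$basis
  cl <- classify_lda(panel$model, scores)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (cls in panel$classes) out[[cls]] <- cl$probabilities[, cls]
  out$predicted <- as.character(cl$predicted)
  out
}

#' Summarize lineage assignments by population
#'
#' @param predicted predicted lineage per sample (character or factor),
#'   e.g. the `predicted` column of [assign_lineages()] output.
#' @param grouping population label per sample.
#' @return A list with `counts` (population x lineage), `percent`
#'   (rows sum to 100), and `overall_percent` (named vector over
#'   lineages, summing to 100).
#' @export
summarize_assignments <- function(predicted, grouping) {
  if (length(predicted) == 0L) stop("no assignments to summarize")
  if (length(predicted) != length(grouping)) {
    stop("predicted and grouping must have equal length")
  }
  counts <- unclass(table(population = grouping, lineage = predicted))
  percent <- 100 * counts / rowSums(counts)
  overall <- colSums(counts)
  list(counts = counts, percent = percent,
       overall_percent = 100 * overall / sum(overall))
}

#' Write a lineage panel to a portable text file
#'
#' Versioned plain-text key-value + matrix-block format
#' (`wingmorph-panel v1`), lossless at full double precision.
#'
#' @param panel a `lineage_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wmat <- function(name, m) {
    m <- as.matrix(m)
    wl("matrix ", name, " ", nrow(m), " ", ncol(m))
    for (i in seq_len(nrow(m))) wl(paste(fmt_num(m[i, ]), collapse = " "))
  }
  wl("wingmorph-panel v1")
  wl("k ", panel$k)
  wl("m_retain ", panel$m_retain)
  wl("projected ", panel$projected)
  wl("classes ", paste(panel$classes, collapse = " "))
  wl("priors ", paste(fmt_num(panel$model$priors), collapse = " "))
  wl("counts ", paste(panel$model$counts, collapse = " "))
  wmat("consensus", matrix(panel$consensus, 1L))
  wmat("center", matrix(panel$center, 1L))
  wmat("basis", panel$basis)
  wmat("class_means", panel$model$class_means)
  wmat("pooled_cov", panel$model$pooled_cov)
  invisible(path)
}

#' Read a lineage panel written by [write_panel()]
#'
#' @param path path to a panel file.
#' @return A `lineage_panel`.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1L] != "wingmorph-panel v1") {
    stop("not a wingmorph panel file (missing 'wingmorph-panel v1' header)")
  }
  kv <- list()
  mats <- list()
  i <- 2L
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], " ")[[1L]]
    if (parts[1L] == "matrix") {
      nm <- parts[2L]
      nr <- as.integer(parts[3L])
      vals <- lapply(lines[i + seq_len(nr)], function(l) {
        as.numeric(strsplit(l, " ")[[1L]])
      })
      mats[[nm]] <- do.call(rbind, vals)
      i <- i + nr + 1L
    } else {
      kv[[parts[1L]]] <- parts[-1L]
      i <- i + 1L
    }
  }
  classes <- kv$classes
  class_means <- mats$class_means
  rownames(class_means) <- classes
  model <- structure(
    list(classes = classes, class_means = class_means,
         pooled_cov = mats$pooled_cov,
         axes = NULL, axis_eigenvalues = NULL,
         priors = stats::setNames(as.numeric(kv$priors), classes),
         counts = as.integer(kv$counts),
         n = sum(as.integer(kv$counts)), m = ncol(class_means)),
    class = "lda_model"
  )
  structure(
    list(consensus = drop(mats$consensus), center = drop(mats$center),
         basis = mats$basis, m_retain = as.integer(kv$m_retain),
         projected = as.logical(kv$projected), k = as.integer(kv$k),
         model = model, classes = classes),
    class = "lineage_panel"
  )
}
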