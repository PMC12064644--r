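## End-to-end orchestration: align -> aggregate -> ordinate -> classify /
## distance / regression / clustering (/ lineage assignment), with every
## table written as labeled CSV and a machine-readable manifest.

#' Run the full wing-morphometrics pipeline
#'
#' Executes the standard analysis graph on a landmark dataset: GPA
#' alignment, averaging into analysis units (colony means, or transect
#' chunks when `chunk_size` is given), PCA truncation, leave-one-out
#' discriminant classification, pairwise Mahalanobis distances, PCoA of
#' those distances, MANOVA with permutation-tested pairwise comparisons,
#' shape-on-geography regression, and BIC-selected model-based
#' clustering; optionally lineage assignment against a reference panel.
#' A stage failure halts with the stage name; tables already written are
#' retained.
#'
#' @param dataset a [landmark_dataset()] or path to a landmarks CSV.
#' @param out_dir output directory (created if needed).
#' @param group_by metadata column defining analysis units (default
#'   `"colony_id"`).
#' @param label_by metadata column defining the populations compared
#'   (default `"population"`).
#' @param chunk_size if not `NULL`, specimens are partitioned into
#'   transect chunks of this size instead of `group_by` units.
#' @param m_retain principal components retained for discriminant
#'   analysis (default 34, i.e. 2k - 4 for 19 landmarks; capped at the
#'   feasible maximum for the data).
#' @param variance_frac variance fraction selecting the clustering
#'   subspace (default 0.95).
#' @param n_perm_regress,n_perm_pairwise permutation counts.
#' @param kmax largest cluster count tried.
#' @param panel optional `lineage_panel` (or path to a panel file) for
#'   lineage assignment.
#' @param seed integer seed recorded in the manifest and used for all
#'   permutation tests.
#' @return A list of stage results (invisibly also written under
#'   `out_dir`).
#' @export
run_full_pipeline <- function(dataset, out_dir,
                              group_by = "colony_id",
                              label_by = "population",
                              chunk_size = NULL,
                              m_retain = 34L,
                              variance_frac = 0.95,
                              n_perm_regress = 999L,
                              n_perm_pairwise = 999L,
                              kmax = 9L,
                              panel = NULL,
                              seed = 1L) {
  if (is.character(dataset)) dataset <- read_landmarks_csv(dataset)
  if (is.character(panel)) panel <- read_panel(panel)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()

  fit <- stage("align", align_gpa(dataset))
  aligned_df <- cbind(fit$meta,
                      centroid_size = fit$centroid_sizes,
                      as.data.frame(fit$aligned))
  utils::write.csv(aligned_df, file.path(out_dir, "aligned.csv"),
                   row.names = FALSE)
  results$alignment <- fit

  samples <- stage("aggregate", {
    if (!is.null(chunk_size)) {
      average_within_groups(fit, chunk_transect(dataset, chunk_size))
    } else {
      if (!group_by %in% names(fit$meta)) {
        stop("grouping column '", group_by, "' not found in metadata")
      }
      average_within_groups(fit, group_by)
    }
  })
  utils::write.csv(cbind(samples$meta, as.data.frame(samples$mean_shapes)),
                   file.path(out_dir, "samples.csv"), row.names = FALSE)
  results$samples <- samples

  labels <- samples$meta[[if (label_by == "population") "population" else label_by]]
  if (is.null(labels)) stop("pipeline stage 'labels' failed: column '",
                            label_by, "' not found")
  n_units <- nrow(samples$mean_shapes)
  g <- length(unique(labels))

  pca <- stage("pca", {
    m_max <- min(n_units - 1L, ncol(samples$mean_shapes))
    shape_pca(samples$mean_shapes, m_retain = min(m_retain, m_max))
  })
  utils::write.csv(as.data.frame(pca$scores),
                   file.path(out_dir, "pca_scores.csv"))
  results$pca <- pca

  m_disc <- min(pca$m_retained, n_units - g - 1L)
  disc_scores <- pca$scores[, seq_len(m_disc), drop = FALSE]

  if (g >= 2L && all(table(labels) >= 3L)) {
    model <- stage("discriminant", fit_lda(disc_scores, labels))
    conf <- stage("classify-cv", loocv_lda(disc_scores, labels))
    dists <- stage("distances", mahalanobis_pairwise(model))
    write_matrix_csv(conf$counts, file.path(out_dir, "confusion.csv"))
    write_matrix_csv(dists, file.path(out_dir, "distances.csv"))
    results$model <- model
    results$confusion <- conf
    results$distances <- dists

    pcoa <- stage("pcoa", shape_pcoa(dists))
    utils::write.csv(as.data.frame(pcoa$coordinates),
                     file.path(out_dir, "pcoa.csv"))
    results$pcoa <- pcoa

    # pairwise tests need an invertible total SSCP within the smallest pair
    sizes <- sort(table(labels))
    m_manova <- min(m_disc, sum(sizes[1:2]) - 3L)
    results$manova <- stage("manova",
      manova_populations(disc_scores[, seq_len(m_manova), drop = FALSE],
                         labels, n_perm = n_perm_pairwise, seed = seed))
    write_matrix_csv(results$manova$pairwise_p,
                     file.path(out_dir, "pairwise_p.csv"))
  }

  if (!anyNA(samples$meta$latitude)) {
    results$regression <- stage("regress",
      regress_shape_rrpp(samples$mean_shapes,
                         samples$meta[, c("latitude", "longitude")],
                         n_perm = n_perm_regress, seed = seed))
    utils::write.csv(results$regression$aov_table,
                     file.path(out_dir, "regression.csv"), row.names = FALSE)
  }

  results$clustering <- stage("cluster", {
    m_clust <- variance_threshold_components(pca$eigenvalues, variance_frac)
    m_clust <- min(m_clust, pca$m_retained)
    select_model_bic(pca$scores[, seq_len(m_clust), drop = FALSE],
                     K_range = seq_len(kmax), seed = seed)
  })
  utils::write.csv(results$clustering$bic_table,
                   file.path(out_dir, "bic_table.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = samples$meta$sample_id,
               cluster = max.col(results$clustering$responsibilities,
                                 ties.method = "first")),
    file.path(out_dir, "cluster_assignments.csv"), row.names = FALSE)

  if (!is.null(panel)) {
    results$assignments <- stage("assign", assign_lineages(panel, samples))
    utils::write.csv(results$assignments,
                     file.path(out_dir, "lineage_assignments.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wingmorph")),
    n_specimens = n_specimens(dataset),
    n_units = n_units,
    group_by = if (is.null(chunk_size)) group_by else
      paste0("transect chunks of ", chunk_size),
    label_by = label_by,
    m_retain = pca$m_retained,
    variance_frac = variance_frac,
    n_perm_regress = n_perm_regress,
    n_perm_pairwise = n_perm_pairwise,
    seed = seed,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
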