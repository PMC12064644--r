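## Synthetic landmark data with known truth.
##
## Emulates the sampling design the analysis assumes: populations with a
## specified pairwise Mahalanobis separation, colonies of ~12 workers,
## digitization noise per landmark, and an optional latitude-linked shape
## gradient. Population effects, colony effects and the gradient live in
## the tangent space at a fixed wing template (orthogonal to the
## translation, rotation and scale generators), so true Mahalanobis
## separations are well-defined in shape space and comparable to what the
## pipeline estimates from colony means.

#' Synthetic dataset configuration
#'
#' @param n_populations number of populations.
#' @param colonies_per_population colonies sampled per population.
#' @param workers_per_colony workers (wings) per colony; default 12, the
#'   typical colony sample size in field surveys.
#' @param pairwise_D target true pairwise Mahalanobis distance between
#'   population mean shapes at the colony-mean level (the analysis unit);
#'   0 gives identical populations.
#' @param colony_sd between-colony shape standard deviation per tangent
#'   coordinate (template units; template centroid size is 1).
#' @param worker_sd within-colony (between-worker) shape sd.
#' @param digitization_sd landmark digitization noise sd, added per
#'   coordinate in image units after the random similarity transform.
#' @param latitude_gradient magnitude of shape change per degree of
#'   latitude along a fixed tangent direction; 0 disables the gradient.
#'   The default makes the geographic signal comparable, relative to
#'   colony-level noise, to latitude effects reported for real transects
#'   (multivariate F near 10 at a couple hundred colonies).
#' @param lat_range,lon_range geographic extent (decimal degrees) over
#'   which colonies are placed.
#' @param scale_range range of random image scales applied per specimen
#'   (the alignment must undo them).
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_populations = 4L,
                             colonies_per_population = 25L,
                             workers_per_colony = 12L,
                             pairwise_D = 8,
                             colony_sd = 0.004,
                             worker_sd = 0.006,
                             digitization_sd = 0.003,
                             latitude_gradient = 0.01,
                             lat_range = c(17, 19),
                             lon_range = c(-94, -91),
                             scale_range = c(0.9, 1.1),
                             seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              colonies_per_population = as.integer(colonies_per_population),
              workers_per_colony = as.integer(workers_per_colony),
              pairwise_D = pairwise_D, colony_sd = colony_sd,
              worker_sd = worker_sd, digitization_sd = digitization_sd,
              latitude_gradient = latitude_gradient,
              lat_range = lat_range, lon_range = lon_range,
              scale_range = scale_range, seed = as.integer(seed))
  if (any(c(cfg$colony_sd, cfg$worker_sd, cfg$digitization_sd) < 0)) {
    stop("standard deviations must be non-negative")
  }
  if (cfg$n_populations < 1L || cfg$colonies_per_population < 1L ||
      cfg$workers_per_colony < 1L) {
    stop("counts must be >= 1")
  }
  if (cfg$pairwise_D < 0) stop("pairwise_D must be non-negative")
  structure(cfg, class = "synthetic_config")
}

## Orthonormal basis of the similarity directions at a centered,
## unit-size template c0 (2k vectors): x-translation, y-translation,
## scale (c0 itself), rotation (90-degree per-landmark rotation of c0).
similarity_basis <- function(template_vec) {
  k <- length(template_vec) / 2L
  tx <- rep(c(1, 0), k) / sqrt(k)
  ty <- rep(c(0, 1), k) / sqrt(k)
  sc <- template_vec
  m <- config_matrix(template_vec)
  rot <- config_vector(cbind(-m[, 2L], m[, 1L]))
  cbind(tx, ty, sc, rot / sqrt(sum(rot^2)))
}

## Project vectors (columns) onto the tangent space at the template and
## Gram-Schmidt orthonormalize them.
tangent_directions <- function(raw, q_sim) {
  proj <- raw - q_sim %*% crossprod(q_sim, raw)
  out <- matrix(0, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- proj[, j]
    if (j > 1L) {
      prev <- out[, seq_len(j - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    out[, j] <- v / sqrt(sum(v^2))
  }
  out
}

#' Simulate a hierarchical landmark dataset with known truth
#'
#' Builds workers as template + population effect + colony effect +
#' latitude-gradient term + worker noise (all in the tangent space at the
#' template), applies a random similarity transform (rotation,
#' translation, scale) per specimen, and adds digitization noise per
#' landmark. Population mean offsets are scaled so that the true pairwise
#' Mahalanobis distance between populations — under the colony-mean
#' covariance `colony_sd^2 + (worker_sd^2 + digitization_sd^2) / workers`
#' per tangent coordinate — equals `pairwise_D` for every pair.
#' Populations occupy adjacent longitude bands and share the latitude
#' range, so the gradient adds within-population variance without
#' confounding population means.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `dataset` (a [landmark_dataset()]) and `truth`
#'   (class `synthetic_truth`: `template`, `population_means` (tangent
#'   offsets added to the template), `true_pairwise_D`, `colony_offsets`,
#'   `gradient` vector, `colony_mean_sd`, `seed`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    template <- center_scale(wing_template())
    tvec <- config_vector(template)
    two_k <- length(tvec)
    q_sim <- similarity_basis(tvec)

    n_dirs <- cfg$n_populations + 1L  # population directions + gradient
    dirs <- tangent_directions(
      matrix(stats::rnorm(two_k * n_dirs), two_k, n_dirs), q_sim)
    grad_dir <- dirs[, n_dirs]
    pop_dirs <- dirs[, seq_len(cfg$n_populations), drop = FALSE]

    s_colony_mean <- sqrt(cfg$colony_sd^2 +
      (cfg$worker_sd^2 + cfg$digitization_sd^2) / cfg$workers_per_colony)
    d_sep <- cfg$pairwise_D * s_colony_mean
    pop_offsets <- pop_dirs * d_sep / sqrt(2)
    pops <- paste0("pop_", seq_len(cfg$n_populations))
    colnames(pop_offsets) <- pops

    true_d <- matrix(cfg$pairwise_D, cfg$n_populations, cfg$n_populations,
                     dimnames = list(pops, pops))
    diag(true_d) <- 0

    lat_mid <- mean(cfg$lat_range)
    lon_width <- diff(cfg$lon_range) / cfg$n_populations
    gradient <- cfg$latitude_gradient * grad_dir

    rows <- list()
    coords <- list()
    colony_offsets <- list()
    idx <- 0L
    n_sites <- max(1L, cfg$colonies_per_population %/% 5L)
    for (p in seq_len(cfg$n_populations)) {
      for (co in seq_len(cfg$colonies_per_population)) {
        colony_id <- sprintf("%s_col%03d", pops[p], co)
        lat <- stats::runif(1L, cfg$lat_range[1L], cfg$lat_range[2L])
        lon <- stats::runif(1L, cfg$lon_range[1L] + (p - 1L) * lon_width,
                            cfg$lon_range[1L] + p * lon_width)
        site <- sprintf("%s_site%02d", pops[p], 1L + (co - 1L) %% n_sites)
        region <- c("south", "middle", "north")[
          1L + findInterval(lat, cfg$lat_range[1L] +
                              diff(cfg$lat_range) * c(1, 2) / 3)]
        col_off <- cfg$colony_sd * drop(
          tangent_project_noise(stats::rnorm(two_k), q_sim))
        colony_offsets[[colony_id]] <- col_off
        colony_mean <- tvec + pop_offsets[, p] + col_off +
          gradient * (lat - lat_mid)
        for (wk in seq_len(cfg$workers_per_colony)) {
          idx <- idx + 1L
          shape <- colony_mean + cfg$worker_sd * stats::rnorm(two_k)
          mat <- config_matrix(shape)
          ang <- stats::runif(1L, 0, 2 * pi)
          rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
          scl <- stats::runif(1L, cfg$scale_range[1L], cfg$scale_range[2L])
          shift <- stats::runif(2L, -1, 1)
          mat <- scl * mat %*% rot
          mat <- sweep(mat, 2L, -shift)
          mat <- mat + cfg$digitization_sd * matrix(stats::rnorm(two_k), ncol = 2L)
          coords[[idx]] <- config_vector(mat)
          rows[[idx]] <- data.frame(
            specimen_id = sprintf("%s_w%02d", colony_id, wk),
            colony_id = colony_id, site_id = site, region = region,
            latitude = lat, longitude = lon, population = pops[p],
            stringsAsFactors = FALSE)
        }
      }
    }
    dataset <- landmark_dataset(do.call(rbind, coords), do.call(rbind, rows))
    truth <- structure(
      list(template = tvec, population_means = pop_offsets,
           true_pairwise_D = true_d, colony_offsets = colony_offsets,
           gradient = gradient, colony_mean_sd = s_colony_mean,
           worker_sd = cfg$worker_sd, seed = cfg$seed),
      class = "synthetic_truth")
    list(dataset = dataset, truth = truth)
  })
}

## project a noise vector onto the tangent space (no renormalization)
tangent_project_noise <- function(v, q_sim) {
  v - q_sim %*% crossprod(q_sim, v)
}

#' Simulate clustered analysis-unit features with known truth
#'
#' Draws colony-mean-level feature vectors (e.g. the principal-component
#' scores the clustering stage consumes) from `n_clusters` spherical
#' Gaussian components with unit within-cluster variance and every pair
#' of cluster means exactly `separation` apart in Mahalanobis distance.
#' Used to validate cluster-count selection and membership recovery
#' against generator truth.
#'
#' @param n_clusters number of clusters (<= m).
#' @param per_cluster samples per cluster.
#' @param m feature dimensionality.
#' @param separation pairwise Mahalanobis distance between cluster means.
#' @param seed integer seed.
#' @return A list with `features` (n x m) and `cluster` (true labels).
#' @export
simulate_cluster_features <- function(n_clusters, per_cluster, m,
                                      separation, seed = 1L) {
  if (n_clusters > m) stop("need m >= n_clusters")
  with_seed(seed, {
    raw <- matrix(stats::rnorm(m * n_clusters), m, n_clusters)
    dirs <- qr.Q(qr(raw))[, seq_len(n_clusters), drop = FALSE]
    means <- t(dirs) * separation / sqrt(2)
    n <- n_clusters * per_cluster
    cluster <- rep(seq_len(n_clusters), each = per_cluster)
    features <- means[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n * m), n, m)
    list(features = features, cluster = cluster)
  })
}

#' Simulate hybrid specimens between two parental populations
#'
#' Draws `n` workers around the convex combination
#' `alpha * mean(parent 1) + (1 - alpha) * mean(parent 2)` with the
#' generator's worker-level noise; hybrids manifest a phenotype
#' intermediate between the parental populations.
#'
#' @param truth a `synthetic_truth` from [simulate_dataset()].
#' @param parents character vector of two population names present in
#'   the truth.
#' @param alpha mixing weight on the first parent, in `[0, 1]`.
#' @param n number of hybrid specimens.
#' @param seed integer seed.
#' @return A [landmark_dataset()] with population label `"hybrid"`.
#' @export
inject_hybrids <- function(truth, parents, alpha, n, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (length(parents) != 2L ||
      !all(parents %in% colnames(truth$population_means))) {
    stop("parents must name two populations present in the truth")
  }
  with_seed(seed, {
    mix <- alpha * truth$population_means[, parents[1L]] +
      (1 - alpha) * truth$population_means[, parents[2L]]
    base <- truth$template + mix
    two_k <- length(base)
    coords <- t(vapply(seq_len(n), function(i) {
      base + truth$worker_sd * stats::rnorm(two_k)
    }, numeric(two_k)))
    meta <- data.frame(
      specimen_id = sprintf("hybrid_%03d", seq_len(n)),
      colony_id = "hybrid", site_id = "hybrid", region = NA,
      latitude = NA_real_, longitude = NA_real_, population = "hybrid",
      stringsAsFactors = FALSE)
    landmark_dataset(coords, meta)
  })
}
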