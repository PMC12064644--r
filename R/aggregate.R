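## Analysis units: wings from one colony are genetically related and not
## independent, so aligned coordinates are averaged within colonies; wings
## collected singly along a transect are pooled into consecutive
## fixed-size samples ordered along the dominant geographic axis.

#' Average aligned shapes within groups
#'
#' Computes the coordinate-wise mean of aligned rows per group (e.g. per
#' colony), with group latitude/longitude the mean of member values and
#' categorical metadata the modal value among members.
#'
#' @param fit a `gpa_fit` (with metadata) or an n x 2k aligned matrix.
#' @param grouping named character vector or factor mapping every
#'   specimen (names = specimen ids, or positional) to a group; or the
#'   name of a metadata column (e.g. `"colony_id"`) when `fit` carries
#'   metadata.
#' @return An object of class `sample_table`: `mean_shapes` (g x 2k, row
#'   names = group ids), `meta` (per-group data frame with `sample_id`,
#'   `n_members`, averaged `latitude`/`longitude`, modal `site_id`,
#'   `region`, `population`), and `members` (list of specimen ids).
#' @export
average_within_groups <- function(fit, grouping) {
  if (inherits(fit, "gpa_fit")) {
    aligned <- fit$aligned
    meta <- fit$meta
  } else {
    aligned <- as.matrix(fit)
    meta <- NULL
  }
  n <- nrow(aligned)
  if (is.character(grouping) && length(grouping) == 1L && !is.null(meta) &&
      grouping %in% names(meta)) {
    grouping <- stats::setNames(as.character(meta[[grouping]]),
                                meta$specimen_id)
  }
  ids <- if (!is.null(meta)) meta$specimen_id else rownames(aligned)
  if (!is.null(names(grouping)) && !is.null(ids)) {
    unmapped <- setdiff(ids, names(grouping))
    if (length(unmapped) > 0L) {
      stop("unmapped specimen(s): ", paste(unmapped, collapse = ", "))
    }
    grouping <- grouping[ids]
  } else if (length(grouping) != n) {
    stop("grouping must map every specimen (length ", n, ")")
  }
  grouping <- as.character(grouping)
  if (anyNA(grouping)) stop("unmapped specimen(s): grouping contains NA")
  groups <- unique(grouping)

  modal <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA)
    names(sort(table(v), decreasing = TRUE))[1L]
  }
  mean_shapes <- matrix(NA_real_, length(groups), ncol(aligned),
                        dimnames = list(groups, colnames(aligned)))
  members <- vector("list", length(groups))
  names(members) <- groups
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    sel <- which(grouping == groups[gi])
    mean_shapes[gi, ] <- colMeans(aligned[sel, , drop = FALSE])
    members[[gi]] <- if (!is.null(ids)) ids[sel] else sel
    rows[[gi]] <- data.frame(
      sample_id = groups[gi],
      n_members = length(sel),
      latitude = if (!is.null(meta)) mean(meta$latitude[sel]) else NA_real_,
      longitude = if (!is.null(meta)) mean(meta$longitude[sel]) else NA_real_,
      site_id = if (!is.null(meta)) modal(meta$site_id[sel]) else NA,
      region = if (!is.null(meta)) modal(meta$region[sel]) else NA,
      population = if (!is.null(meta)) modal(meta$population[sel]) else NA,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(mean_shapes = mean_shapes,
         meta = do.call(rbind, rows),
         members = members),
    class = "sample_table"
  )
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table:", nrow(x$mean_shapes), "samples (sizes",
      paste(range(x$meta$n_members), collapse = "-"), ")\n")
  invisible(x)
}

#' Partition transect specimens into consecutive fixed-size samples
#'
#' Orders specimens along the first principal axis of their geographic
#' coordinates (ties broken by latitude, then longitude, then specimen
#' id) and partitions them sequentially into chunks of `size`; the final
#' chunk keeps the remainder. The ordering is deterministic, so chunk
#' membership does not depend on input row order.
#'
#' @param dataset a [landmark_dataset()] (or any object with a `meta`
#'   data frame containing `specimen_id`, `latitude`, `longitude`).
#' @param size chunk size (>= 1); e.g. 10 wings per sample.
#' @return Named character vector mapping specimen id to chunk id
#'   (`"chunk_01"`, ...), in transect order.
#' @export
chunk_transect <- function(dataset, size) {
  if (size < 1L) stop("size must be >= 1")
  meta <- if (is.data.frame(dataset)) dataset else dataset$meta
  n <- nrow(meta)
  if (is.null(n) || n == 0L) stop("empty dataset")
  lat <- meta$latitude
  lon <- meta$longitude
  if (anyNA(lat) || anyNA(lon)) {
    stop("latitude/longitude required for transect chunking")
  }
  geo <- cbind(lat, lon)
  geo_c <- sweep(geo, 2L, colMeans(geo))
  cv <- crossprod(geo_c) / max(1L, n - 1L)
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  score <- drop(geo_c %*% axis)
  ord <- order(score, lat, lon, meta$specimen_id)
  n_chunks <- ceiling(n / size)
  chunk_ids <- sprintf("chunk_%02d", rep(seq_len(n_chunks), each = size)[seq_len(n)])
  stats::setNames(chunk_ids, meta$specimen_id[ord])
}
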