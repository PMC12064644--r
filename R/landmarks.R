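#' @keywords internal
"_PACKAGE"

## Coordinate conventions used throughout:
##  - a single configuration is a k x 2 matrix (columns x, y), or the
##    equivalent length-2k vector ordered (x1, y1, x2, y2, ...);
##  - a set of n configurations is an n x 2k matrix whose columns are named
##    x1, y1, ..., xk, yk.

#' Convert a configuration between matrix and vector layout
#'
#' @param v numeric vector of length 2k ordered `(x1, y1, ..., xk, yk)`.
#' @return `config_matrix()`: a k x 2 matrix; `config_vector()`: a 2k vector.
#' @keywords internal
#' @noRd
config_matrix <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' @noRd
config_vector <- function(m) {
  as.vector(t(m))
}

coord_colnames <- function(k) {
  as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
}

#' Metadata columns every landmark dataset carries
#' @noRd
META_COLS <- c("specimen_id", "colony_id", "site_id", "region",
               "latitude", "longitude", "population")

#' Construct a landmark dataset
#'
#' Bundles an n x 2k coordinate matrix with one metadata record per
#' specimen. The landmark order is fixed and meaningful: column pair i is
#' always the same anatomical point (for the honey bee forewing standard,
#' one of the 19 vein junctions).
#'
#' @param coords numeric matrix, n specimens by 2k coordinates, columns
#'   ordered `x1, y1, ..., xk, yk`. All values must be finite.
#' @param meta data frame with columns `specimen_id`, `colony_id`,
#'   `site_id`, `region`, `latitude`, `longitude`, `population`. Missing
#'   columns are filled with `NA`; `specimen_id` is mandatory and must be
#'   unique.
#' @return An object of class `landmark_dataset` with elements `coords`,
#'   `meta` and `k`.
#' @export
landmark_dataset <- function(coords, meta) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) %% 2L != 0L) {
    stop("coordinate matrix must have an even number of columns (x,y pairs)")
  }
  k <- ncol(coords) / 2L
  if (k < 3L) stop("at least 3 landmarks are required, got ", k)
  if (!all(is.finite(coords))) stop("all landmark coordinates must be finite")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(meta)) stop("metadata must contain 'specimen_id'")
  meta$specimen_id <- as.character(meta$specimen_id)
  if (anyDuplicated(meta$specimen_id)) {
    stop("specimen_id values must be unique within a dataset")
  }
  if (nrow(meta) != nrow(coords)) {
    stop("one metadata record per configuration required: ",
         nrow(meta), " metadata rows vs ", nrow(coords), " configurations")
  }
  for (col in setdiff(META_COLS, names(meta))) meta[[col]] <- NA
  meta$latitude <- as.numeric(meta$latitude)
  meta$longitude <- as.numeric(meta$longitude)
  lat <- meta$latitude
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) {
    stop("latitude must lie in [-90, 90]")
  }
  lon <- meta$longitude
  if (any(!is.na(lon) & (lon < -180 | lon > 180))) {
    stop("longitude must lie in [-180, 180]")
  }
  colnames(coords) <- coord_colnames(k)
  rownames(coords) <- meta$specimen_id
  structure(
    list(coords = coords, meta = meta[, META_COLS, drop = FALSE], k = k),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("landmark_dataset:", nrow(x$coords), "configurations,",
      x$k, "landmarks\n")
  pops <- unique(x$meta$population)
  if (!all(is.na(pops))) cat("populations:", paste(pops, collapse = ", "), "\n")
  invisible(x)
}

#' Number of specimens in a dataset
#' @param x a `landmark_dataset`.
#' @export
n_specimens <- function(x) nrow(x$coords)

#' Built-in 19-landmark forewing template
#'
#' A synthetic but geometrically plausible honey bee forewing venation
#' layout: 19 vein-junction landmarks on a wing roughly three times longer
#' than wide, in arbitrary image units. It is a base shape for the
#' synthetic-data generator and carries no claim of being a measured wing.
#'
#' @return A 19 x 2 coordinate matrix.
#' @export
wing_template <- function() {
  pts <- matrix(c(
    0.90, 1.45,   # 1  wing base, junction of costal and radial veins
    1.80, 1.90,   # 2
    2.60, 2.20,   # 3
    3.40, 2.45,   # 4  anterior (leading-edge) vein junctions
    4.30, 2.55,   # 5
    5.20, 2.50,   # 6
    6.10, 2.30,   # 7
    2.30, 1.50,   # 8
    3.10, 1.70,   # 9
    4.00, 1.85,   # 10 median vein junctions
    4.90, 1.90,   # 11
    5.80, 1.80,   # 12
    6.70, 1.60,   # 13
    2.90, 1.10,   # 14
    3.80, 1.15,   # 15 posterior (cubital/anal) junctions
    4.70, 1.20,   # 16
    5.60, 1.10,   # 17
    6.50, 0.95,   # 18
    7.40, 1.35    # 19 distal end of radial cell
  ), ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  pts
}
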