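## Text I/O for landmark datasets and analysis tables.
##
## The canonical dataset format is a CSV with one row per specimen:
## metadata columns first, then interleaved coordinate columns
## x1,y1,...,xk,yk. TPS is supported for interchange with other
## morphometrics software. All numeric output uses "%.17g" so that
## write -> read round trips are lossless.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a landmark dataset from CSV
#'
#' Expects a header with `specimen_id`, optional metadata columns, and
#' coordinate columns `x1,y1,...,xk,yk` (any column order; k is inferred
#' from the header). Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return A [landmark_dataset()].
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  coord_cols <- grep("^[xy][0-9]+$", nm, value = TRUE)
  idx <- as.integer(sub("^[xy]", "", coord_cols))
  if (length(idx) == 0L) stop("format error: no coordinate columns (x1,y1,...) found")
  k <- max(idx)
  want <- coord_colnames(k)
  missing <- setdiff(want, coord_cols)
  if (length(missing) > 0L) {
    stop("format error: missing coordinate column(s): ",
         paste(missing, collapse = ", "))
  }
  coords <- matrix(NA_real_, nrow(df), 2L * k)
  for (j in seq_along(want)) {
    v <- df[[want[j]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad) > 0L) {
      stop("parse error: non-numeric value in column ", want[j],
           " at row ", bad[1L])
    }
    coords[, j] <- num
  }
  if (anyNA(coords)) stop("parse error: missing coordinate values")
  meta <- df[, setdiff(nm, want), drop = FALSE]
  landmark_dataset(coords, meta)
}

#' Write a landmark dataset to CSV
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  out <- dataset$meta
  co <- dataset$coords
  for (j in seq_len(ncol(co))) out[[colnames(co)[j]]] <- fmt_num(co[, j])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the standard TPS dialect: records of `LM=k`, k lines of
#' `x y` coordinates, an optional `SCALE=s` (coordinates multiplied by s)
#' and an `ID=name` line. Blank lines between records are tolerated.
#'
#' @param path path to a TPS file.
#' @return A list of configurations, each a list with `specimen_id` and
#'   `points` (k x 2 matrix). Records may have differing k; uniformity is
#'   only enforced when a dataset is assembled.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  configs <- list()
  i <- 1L
  rec <- 0L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      stop("format error: expected 'LM=' at line ", i)
    }
    rec <- rec + 1L
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    i <- i + 1L
    pts <- matrix(NA_real_, k, 2L)
    got <- 0L
    while (i <= n && grepl("^[-+0-9.eE]+\\s+[-+0-9.eE]+$", lines[i])) {
      got <- got + 1L
      if (got > k) break
      xy <- as.numeric(strsplit(lines[i], "\\s+")[[1L]])
      pts[got, ] <- xy
      i <- i + 1L
    }
    if (got != k) {
      stop("format error in record ", rec, ": LM=", k,
           " but ", got, " coordinate lines found")
    }
    id <- paste0("tps_", rec)
    scale <- NA_real_
    while (i <= n && lines[i] != "" &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i],
                                ignore.case = TRUE))
      }
      i <- i + 1L
    }
    if (!is.na(scale)) pts <- pts * scale
    colnames(pts) <- c("x", "y")
    configs[[rec]] <- list(specimen_id = id, points = pts)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' @param configs a list of configurations (`specimen_id`, `points`), or a
#'   [landmark_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_dataset")) {
    ids <- configs$meta$specimen_id
    configs <- lapply(seq_len(nrow(configs$coords)), function(i) {
      list(specimen_id = ids[i], points = config_matrix(configs$coords[i, ]))
    })
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    pts <- cf$points
    writeLines(paste0("LM=", nrow(pts)), con)
    writeLines(paste(fmt_num(pts[, 1L]), fmt_num(pts[, 2L])), con)
    writeLines(paste0("ID=", cf$specimen_id), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a labeled matrix to CSV at full precision
#'
#' Serializes distance matrices, confusion matrices and similar labeled
#' tables so that [read_matrix_csv()] recovers them losslessly.
#'
#' @param m numeric matrix with row and column labels (dimnames), or
#'   labels supplied via `labels` for a square matrix.
#' @param path output path.
#' @param labels optional character vector used for both dimensions of a
#'   square matrix; overrides existing dimnames.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, labels = NULL) {
  m <- as.matrix(m)
  if (!is.null(labels)) {
    if (nrow(m) != ncol(m) || length(labels) != nrow(m)) {
      stop("labels length must match the dimensions of a square matrix")
    }
    dimnames(m) <- list(labels, labels)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry row and column labels")
  }
  lines <- c(
    paste(c("", colnames(m)), collapse = ","),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = ",")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix_csv()]
#'
#' @param path path to the CSV file.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}
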