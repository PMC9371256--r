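#' Write / read a connectivity matrix as tab-delimited text
#'
#' Matrices are stored with a one-line header of region labels. Reading
#' validates that the body is square and numeric and that asymmetries do not
#' exceed `1e-8`; round-tripping reproduces the matrix to full printed
#' precision.
#'
#' @param matrix Square numeric matrix.
#' @param path File path.
#' @param labels Optional region labels (defaults to existing column names
#'   or `V1..VN`).
#' @return `read_matrix()` returns the matrix with dimnames set from the
#'   header.
#' @export
write_matrix <- function(matrix, path, labels = NULL) {
  check_square_symmetric(matrix, tol = 1e-8, what = "matrix to write")
  if (is.null(labels)) {
    labels <- colnames(matrix)
    if (is.null(labels)) labels <- paste0("V", seq_len(ncol(matrix)))
  }
  out <- matrix
  dimnames(out) <- list(NULL, labels)
  utils::write.table(format(out, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  body <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  m <- as.matrix(body)
  if (!is.numeric(m)) stop("matrix body is not numeric: ", path, call. = FALSE)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is not square: %d rows x %d columns",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  rownames(m) <- colnames(m)
  check_square_symmetric(m, tol = 1e-8, what = paste0("matrix in ", path))
  m
}

#' Write / read parcellated time series
#'
#' The values are stored tab-delimited (first column the region label, the
#' remaining columns samples) with a JSON sidecar `<path>.json` holding the
#' sampling rate.
#'
#' @param ts A `parcel_ts`.
#' @param path File path for the values; the sidecar adds `.json`.
#' @return `read_parcel_ts()` returns a `parcel_ts`.
#' @export
write_parcel_ts <- function(ts, path) {
  df <- data.frame(region = ts$labels, ts$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = ts$fs), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parcel_ts
#' @export
read_parcel_ts <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sampling-rate sidecar: ", sidecar,
                                  call. = FALSE)
  fs <- jsonlite::read_json(sidecar)$fs
  body <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
  parcel_ts(as.matrix(body[, -1]), fs = fs, labels = body[[1]])
}

#' Write synthetic ground truth as JSON
#'
#' @param truth A `ground_truth` list.
#' @param path File path.
#' @return `read_ground_truth()` returns the `ground_truth` list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$weights <- as.matrix(raw$weights)
  structure(raw, class = "ground_truth")
}
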