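#' Generate a mirrored two-hemisphere spherical parcellation geometry
#'
#' Places `n_parcels / 2` quasi-uniform points on one unit hemisphere using a
#' Fibonacci lattice (with a seeded random azimuthal offset) and mirrors them
#' across the midline plane `x = 0` to form the other hemisphere. This mimics
#' the spherical projection of a cortical surface parcellation: left and right
#' hemisphere parcels are mirror images, which is what hemisphere-respecting
#' spin rotations require.
#'
#' @param n_parcels Even integer >= 10; total number of parcels.
#' @param seed Integer seed; determines the lattice offset.
#' @return A data frame of class `parcel_geometry` with columns `parcel`
#'   (integer id), `hemi` (`"L"` or `"R"`), and unit-norm coordinates
#'   `x`, `y`, `z`. Left-hemisphere parcels (x < 0) come first.
#' @examples
#' g <- make_geometry(20, seed = 1)
#' range(sqrt(g$x^2 + g$y^2 + g$z^2))
#' @export
make_geometry <- function(n_parcels, seed = 1L) {
  if (n_parcels %% 2 != 0 || n_parcels < 10) {
    stop("n_parcels must be an even integer >= 10", call. = FALSE)
  }
  m <- n_parcels / 2
  offset <- with_seed_(seed, stats::runif(1, 0, 2 * pi))
  k <- seq_len(m) - 0.5
  # polar angle from the +x axis, restricted to one hemisphere (x > 0)
  cos_theta <- k / m
  sin_theta <- sqrt(1 - cos_theta^2)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * seq_len(m) + offset
  right <- cbind(x = cos_theta, y = sin_theta * cos(phi), z = sin_theta * sin(phi))
  left <- right
  left[, "x"] <- -left[, "x"]
  coords <- rbind(left, right)
  out <- data.frame(
    parcel = seq_len(n_parcels),
    hemi = rep(c("L", "R"), each = m),
    x = coords[, "x"], y = coords[, "y"], z = coords[, "z"],
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcel_geometry", "data.frame")
  out
}

#' @keywords internal
#' @noRd
check_geometry <- function(geometry) {
  req <- c("parcel", "hemi", "x", "y", "z")
  if (!all(req %in% names(geometry))) {
    stop("geometry must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  norms <- sqrt(geometry$x^2 + geometry$y^2 + geometry$z^2)
  if (any(abs(norms - 1) > 1e-6)) {
    stop("geometry coordinates must lie on the unit sphere", call. = FALSE)
  }
  if (!all(c("L", "R") %in% geometry$hemi)) {
    stop("both hemispheres must be non-empty", call. = FALSE)
  }
  invisible(geometry)
}

#' Write / read parcel geometry as tab-delimited text
#'
#' @param geometry A `parcel_geometry` data frame.
#' @param path File path.
#' @return `read_geometry()` returns a `parcel_geometry` data frame.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.table(geometry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("parcel_geometry", "data.frame")
  check_geometry(out)
  out
}
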