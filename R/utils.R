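# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' All stochastic operations in the package funnel through this helper so a
#' single integer seed fully determines their output without disturbing the
#' caller's RNG state.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Euclidean distance matrix between parcel centroids
#' @keywords internal
#' @noRd
geometry_dist <- function(geometry) {
  as.matrix(stats::dist(as.matrix(geometry[, c("x", "y", "z")])))
}

#' Sample a smooth map on the parcellated sphere
#'
#' Draws one realization of a Gaussian process with exponential covariance
#' `exp(-d / length_scale)` over the parcel centroids. Used for band-specific
#' spatial modulation, the synthetic hierarchy, and smooth null maps.
#'
#' @param geometry Parcel geometry (`make_geometry()`).
#' @param length_scale Correlation length, in the units of the coordinates.
#' @param n Number of independent maps to draw.
#' @param seed Optional integer seed.
#' @return A numeric vector (`n = 1`) or an `n_parcels x n` matrix.
#' @export
smooth_sphere_map <- function(geometry, length_scale = 0.5, n = 1, seed = NULL) {
  stopifnot(length_scale > 0, n >= 1)
  d <- geometry_dist(geometry)
  cov <- exp(-d / length_scale)
  # jitter keeps the Cholesky stable for near-duplicate centroids
  l <- chol(cov + diag(1e-8, nrow(cov)))
  z <- with_seed_(seed, matrix(stats::rnorm(nrow(cov) * n), nrow(cov), n))
  out <- crossprod(l, z)
  if (n == 1) drop(out) else out
}

#' Symmetrize a square matrix by averaging with its transpose
#' @keywords internal
#' @noRd
symmetrize <- function(m) (m + t(m)) / 2

#' Validate a square symmetric connectivity-like matrix
#' @keywords internal
#' @noRd
check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  asym <- abs(m - t(m))
  if (any(asym > tol, na.rm = TRUE)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("%s is asymmetric at entry (%d, %d): |M[i,j] - M[j,i]| = %.3g",
                 what, idx[1], idx[2], max(asym)), call. = FALSE)
  }
  invisible(m)
}

#' Discrete analytic signal via the FFT
#'
#' Returns the complex analytic signal whose real part is the input and whose
#' modulus is the instantaneous amplitude envelope.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2, all(is.finite(x)))
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}
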