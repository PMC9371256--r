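#' Draw a uniform random 3-D rotation matrix
#'
#' Haar-uniform over SO(3), obtained by QR-orthogonalizing a Gaussian matrix
#' with the sign convention that makes the decomposition unique, then
#' flipping one column if the determinant is negative (a measure-preserving
#' map from the reflection coset onto the rotations).
#'
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a hemisphere-respecting spin ensemble
#'
#' For each repetition, draws a uniform random rotation, applies it to the
#' left hemisphere's spherical coordinates and the midline-mirrored rotation
#' to the right hemisphere, and reassigns every parcel the index of the
#' nearest original parcel (same hemisphere) to its rotated position.
#' Duplicate assignments are permitted. The spun value of parcel `j` under
#' repetition `k` is `map[assignment[k, j]]`.
#'
#' @param geometry Parcel geometry (unit-sphere coordinates, both
#'   hemispheres non-empty).
#' @param n_spin Number of repetitions (>= 1).
#' @param seed Integer seed.
#' @return A `spin_ensemble`: an `n_spin x N` integer matrix with attributes
#'   `seed` and `n_spin`.
#' @export
generate_spins <- function(geometry, n_spin, seed = 1L) {
  check_geometry(geometry)
  if (n_spin < 1) stop("n_spin must be >= 1", call. = FALSE)
  assignment <- matrix(NA_integer_, n_spin, nrow(geometry))
  with_seed_(seed, {
    for (k in seq_len(n_spin)) {
      assignment[k, ] <- spin_once(geometry, random_rotation())
    }
  })
  structure(assignment, class = "spin_ensemble", seed = seed, n_spin = n_spin)
}

#' Nearest-parcel reassignment for one rotation
#' @keywords internal
#' @noRd
spin_once <- function(geometry, rot) {
  coords <- as.matrix(geometry[, c("x", "y", "z")])
  mirror <- diag(c(-1, 1, 1))
  rots <- list(L = rot, R = mirror %*% rot %*% mirror)
  out <- integer(nrow(geometry))
  for (h in c("L", "R")) {
    idx <- which(geometry$hemi == h)
    rotated <- coords[idx, , drop = FALSE] %*% t(rots[[h]])
    # nearest original parcel on the unit sphere = largest dot product
    sim <- rotated %*% t(coords[idx, , drop = FALSE])
    out[idx] <- idx[max.col(sim, ties.method = "first")]
  }
  out
}

#' Spun copies of a map
#' @keywords internal
#' @noRd
spin_maps <- function(map, spins) {
  # N x n_spin matrix; column k is the map under repetition k
  matrix(map[t(spins)], nrow = ncol(spins))
}

#' Spin permutation test for the association of two parcellated maps
#'
#' Correlates the two maps (Spearman rank correlation by default), builds a
#' null distribution by correlating spun copies of `map_a` with the intact
#' `map_b`, and returns the two-tailed permutation p value
#' `p_spin = (1 + #\{|r_null| >= |r_emp|\}) / (n_spin + 1)`.
#'
#' @param map_a,map_b Finite numeric vectors, one value per parcel.
#' @param spins A `spin_ensemble` on the same parcellation.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `null_test` list: `r` (empirical correlation), `nulls`
#'   (length `n_spin`), `p_spin`, `method`.
#' @export
spin_pvalue <- function(map_a, map_b, spins, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- ncol(spins)
  if (length(map_a) != n || length(map_b) != n) {
    stop("maps and spin ensemble disagree on parcellation size", call. = FALSE)
  }
  if (any(!is.finite(map_a)) || any(!is.finite(map_b))) {
    stop("maps must be finite", call. = FALSE)
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("correlation undefined for a constant map", call. = FALSE)
  }
  r_emp <- stats::cor(map_a, map_b, method = method)
  nulls <- drop(stats::cor(spin_maps(map_a, spins), map_b, method = method))
  p <- (1 + sum(abs(nulls) >= abs(r_emp))) / (nrow(spins) + 1)
  structure(list(r = r_emp, nulls = nulls, p_spin = p, method = method),
            class = "null_test")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: sort the p values, find the largest rank `k` with
#' `p_(k) <= (k / m) alpha`, and reject hypotheses at ranks `1..k`.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @param alpha Target false discovery rate.
#' @return A list: `reject` (logical mask in input order), `threshold`
#'   (largest rejected p value, 0 if none), `n_reject`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p values must be finite and in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  sorted <- pvalues[ord]
  below <- which(sorted <= seq_len(m) / m * alpha)
  reject <- logical(m)
  threshold <- 0
  if (length(below) > 0) {
    k <- max(below)
    reject[ord[seq_len(k)]] <- TRUE
    threshold <- sorted[k]
  }
  list(reject = reject, threshold = threshold, n_reject = sum(reject))
}
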