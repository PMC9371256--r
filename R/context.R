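#' Principal functional gradient via diffusion map embedding
#'
#' Follows the standard recipe for cortical functional gradients: each row of
#' the connectivity matrix is thresholded to keep only its top 10% of
#' off-diagonal values; a cosine-similarity matrix is computed between the
#' thresholded rows; negative similarities are clipped to zero to obtain a
#' positive affinity matrix; and a diffusion-map embedding with anisotropic
#' normalization (alpha = 0.5) and eigenvalue-scaled ("automatic") diffusion
#' time is applied. The first non-trivial component orders regions along the
#' principal axis of variation in connectivity.
#'
#' @param fc Symmetric connectivity matrix, N >= 10.
#' @param top_frac Fraction of each row retained (default 0.10).
#' @param anchor Optional map used to fix the gradient's sign (the component
#'   is flipped so its correlation with `anchor` is non-negative). Without an
#'   anchor the entry of largest magnitude is made positive.
#' @return A `gradient_map` list: `scores` (length N), `eigenvalue`,
#'   `component` (= 1), `lambdas` (leading eigenvalues).
#' @export
principal_gradient <- function(fc, top_frac = 0.10, anchor = NULL) {
  n <- nrow(fc)
  if (n < 10) stop("need at least 10 regions", call. = FALSE)
  thr <- threshold_rows(fc, top_frac)
  aff <- cosine_affinity(thr)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(aff > 0, mode = "undirected")
  )
  if (comp$no > 1) {
    warning("affinity graph splits into ", comp$no, " components (sizes ",
            paste(comp$csize, collapse = ", "),
            "); the leading gradient separates components")
  }
  emb <- diffusion_map(aff, n_components = 3)
  scores <- emb$vectors[, 1]
  if (!is.null(anchor)) {
    if (stats::cor(scores, anchor) < 0) scores <- -scores
  } else if (scores[which.max(abs(scores))] < 0) {
    scores <- -scores
  }
  structure(list(scores = scores, eigenvalue = emb$lambdas[1], component = 1L,
                 lambdas = emb$lambdas),
            class = "gradient_map")
}

#' @keywords internal
#' @noRd
threshold_rows <- function(fc, top_frac) {
  n <- nrow(fc)
  k <- ceiling(top_frac * (n - 1))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- fc[i, ]
    row[i] <- -Inf
    keep <- order(-row, seq_len(n))[seq_len(k)]  # ties broken by index order
    out[i, keep] <- fc[i, keep]
  }
  out
}

#' @keywords internal
#' @noRd
cosine_affinity <- function(rows) {
  norms <- sqrt(rowSums(rows^2))
  if (any(norms == 0)) {
    stop("row(s) with no surviving connections: ",
         paste(which(norms == 0), collapse = ", "), call. = FALSE)
  }
  sim <- tcrossprod(rows) / tcrossprod(norms)
  pmax(sim, 0)
}

#' @keywords internal
#' @noRd
diffusion_map <- function(w, alpha = 0.5, n_components = 3) {
  d <- rowSums(w)
  w1 <- w / (outer(d, d)^alpha)
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))
  s <- symmetrize(s)                      # guard against round-off asymmetry
  eig <- eigen(s, symmetric = TRUE)
  vec <- eig$vectors
  # the unit eigenvalue is degenerate when the affinity graph is
  # disconnected; rotate that eigenspace so its first basis vector is the
  # stationary direction sqrt(d1) and the rest (component contrasts) follow
  top <- which(eig$values >= eig$values[1] - 1e-9)
  if (length(top) > 1) {
    v <- vec[, top, drop = FALSE]
    q1 <- drop(v %*% crossprod(v, sqrt(d1)))
    vec[, top] <- qr.Q(qr(cbind(q1, v)))[, seq_along(top)]
  }
  # right eigenvectors of the Markov operator, trivial component dropped;
  # "automatic" diffusion time scales component i by lambda_i / (1 - lambda_i)
  psi <- vec / sqrt(d1)
  psi <- psi / psi[1, 1]                  # normalize so psi_0 is constant 1
  lambdas <- eig$values[-1][seq_len(n_components)]
  scale <- ifelse(lambdas >= 1 - 1e-9, 1, lambdas / (1 - lambdas))
  vectors <- sapply(seq_len(n_components), function(i) {
    psi[, i + 1] * scale[i]
  })
  list(vectors = vectors, lambdas = lambdas)
}

#' Regional structure-function coupling
#'
#' For each region, the Spearman rank correlation between the structural and
#' functional connectivity profiles restricted to the region's nonzero
#' structural connections.
#'
#' @param sc Non-negative structural connectivity matrix.
#' @param fc Functional connectivity matrix on the same parcellation.
#' @return Length-N numeric map; regions with fewer than 3 nonzero
#'   structural connections are `NA` (with a warning).
#' @export
structure_function_coupling <- function(sc, fc) {
  if (!all(dim(sc) == dim(fc))) stop("matrices disagree in size", call. = FALSE)
  if (any(sc < 0)) stop("structural matrix must be non-negative", call. = FALSE)
  n <- nrow(sc)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- regional_profile(sc, i)
    f <- regional_profile(fc, i)
    nz <- which(s != 0)
    if (length(nz) >= 3) {
      out[i] <- stats::cor(s[nz], f[nz], method = "spearman")
    }
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)),
            " region(s) with < 3 nonzero structural connections set to NA")
  }
  out
}

#' Depth-wise association between a cortical map and laminar profiles
#'
#' Correlates the map with the staining-intensity profile at every cortical
#' depth (Spearman), computes a spin permutation p value per depth using a
#' shared [generate_spins()] ensemble, and controls the false discovery rate
#' across depths with [bh_fdr()].
#'
#' @param map Length-N cortical map.
#' @param profiles N x D depth-profile matrix.
#' @param spins A `spin_ensemble`.
#' @param alpha FDR level.
#' @return A list: `r` (length D), `p_spin` (length D), `significant`
#'   (logical mask after FDR), `fdr` (the [bh_fdr()] result).
#' @export
depth_profile_association <- function(map, profiles, spins, alpha = 0.05) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(map)) {
    stop("map and profiles disagree on region count", call. = FALSE)
  }
  tests <- lapply(seq_len(ncol(profiles)), function(d) {
    spin_pvalue(map, profiles[, d], spins)
  })
  r <- vapply(tests, `[[`, numeric(1), "r")
  p <- vapply(tests, `[[`, numeric(1), "p_spin")
  fdr <- bh_fdr(p, alpha)
  list(r = r, p_spin = p, significant = fdr$reject, fdr = fdr)
}

#' Robust sigmoid normalization of expression values
#'
#' `1 / (1 + exp(-(x - median(x)) / iqr_n))` with the normalized
#' interquartile range `iqr_n = IQR(x) / 1.349` (the scaling that makes the
#' IQR consistent with the standard deviation under normality). Maps the
#' median to exactly 0.5 and is robust to outliers.
#'
#' @param x Numeric vector with positive interquartile range.
#' @return Values in (0, 1).
#' @export
robust_sigmoid <- function(x) {
  iqr <- stats::IQR(x) / 1.349
  if (iqr <= 0) stop("zero interquartile range", call. = FALSE)
  1 / (1 + exp(-(x - stats::median(x)) / iqr))
}

#' Rescale values to the unit interval
#'
#' @param x Non-constant numeric vector.
#' @return `(x - min) / (max - min)`.
#' @export
unit_rescale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("constant input cannot be rescaled", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Differential stability of a gene across donors
#'
#' Mean Spearman rank correlation of the gene's regional expression pattern
#' over all donor pairs. Donor pairs involving a constant pattern are
#' excluded with a warning.
#'
#' @param panel An `expression_panel` (named list of donor region x gene
#'   matrices with shared dimnames).
#' @param gene Gene identifier (column name).
#' @return Scalar in `[-1, 1]`.
#' @export
differential_stability <- function(panel, gene) {
  if (length(panel) < 2) stop("need at least 2 donors", call. = FALSE)
  cols <- lapply(panel, function(b) {
    if (!gene %in% colnames(b)) stop("gene not found: ", gene, call. = FALSE)
    b[, gene]
  })
  if (length(cols[[1]]) < 3) stop("need at least 3 regions", call. = FALSE)
  combos <- utils::combn(length(cols), 2)
  rho <- apply(combos, 2, function(pr) {
    a <- cols[[pr[1]]]; b <- cols[[pr[2]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  })
  if (anyNA(rho)) {
    warning(sum(is.na(rho)), " donor pair(s) with constant pattern excluded")
    rho <- rho[!is.na(rho)]
  }
  mean(rho)
}

#' Association between a cortical map and one gene's expression
#'
#' Normalizes the gene's regional expression within each donor (robust
#' sigmoid then unit rescaling), averages across donors, and tests the
#' Spearman association with the map against the spin null.
#'
#' @param map Length-N cortical map.
#' @param panel An `expression_panel`.
#' @param gene Gene identifier.
#' @param spins A `spin_ensemble`.
#' @return A `null_test` (see [spin_pvalue()]) with an extra element
#'   `expression`, the donor-averaged normalized expression map.
#' @export
expression_map_association <- function(map, panel, gene, spins) {
  if (!gene %in% colnames(panel[[1]])) {
    stop("gene not found: ", gene, call. = FALSE)
  }
  norm <- sapply(panel, function(b) unit_rescale(robust_sigmoid(b[, gene])))
  expr <- rowMeans(norm)
  out <- spin_pvalue(map, expr, spins)
  out$expression <- expr
  out
}
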