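#' Configuration for the synthetic multimodal connectivity generator
#'
#' Bundles every tunable of the generator with validated defaults. The
#' generator plants a known region-by-band mixing structure so downstream
#' model fitting, dominance analysis, cross-validation, and null inference
#' can all be checked against an analytic ground truth.
#'
#' @param n_parcels Even integer >= 10; parcels split equally across the two
#'   hemispheres.
#' @param band_names Labels of the six electromagnetic frequency bands.
#' @param decay_length Distance constant of the connectivity decay, in the
#'   units of the geometry coordinates (unit sphere).
#' @param weight_smoothness Spatial correlation length of the smooth maps used
#'   for band modulation, the hierarchy, and the mixing weights.
#' @param noise_profile `"graded"` (per-region noise standard deviations are
#'   solved so the expected variance explained declines linearly along the
#'   synthetic unimodal-to-transmodal hierarchy) or `"constant"`.
#' @param noise_sd_range Length-2 non-negative vector; in the constant
#'   profile its mean is the noise standard deviation everywhere (ignored in
#'   the graded profile).
#' @param target_r2_range Length-2 vector in (0, 1): expected variance
#'   explained at the top and bottom of the hierarchy (graded profile).
#' @param band_modulation Amplitude of band-specific smooth spatial structure
#'   added on top of the distance decay.
#' @param band_noise_sd Standard deviation of the symmetric measurement noise
#'   in each band matrix.
#' @param n_subjects Number of synthetic participants.
#' @param subject_noise_sd Scale of per-subject symmetric deviations from the
#'   group-average matrices.
#' @param seed Integer seed; fully determines all generated outputs.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parcels = 200L,
                             band_names = canonical_bands()$name,
                             decay_length = 0.8,
                             weight_smoothness = 0.5,
                             noise_profile = c("graded", "constant"),
                             noise_sd_range = c(0.02, 0.35),
                             target_r2_range = c(0.05, 0.8),
                             band_modulation = 0.15,
                             band_noise_sd = 0.02,
                             n_subjects = 10L,
                             subject_noise_sd = 0.05,
                             seed = 42L) {
  noise_profile <- match.arg(noise_profile)
  if (n_parcels %% 2 != 0 || n_parcels < 10) {
    stop("n_parcels must be an even integer >= 10", call. = FALSE)
  }
  if (length(band_names) != 6) stop("exactly 6 band names required", call. = FALSE)
  if (!is.numeric(decay_length) || decay_length <= 0) {
    stop("decay_length must be positive", call. = FALSE)
  }
  if (any(noise_sd_range < 0) || length(noise_sd_range) != 2) {
    stop("noise_sd_range must be two non-negative values", call. = FALSE)
  }
  if (length(target_r2_range) != 2 || any(target_r2_range <= 0) ||
      any(target_r2_range >= 1) || target_r2_range[1] >= target_r2_range[2]) {
    stop("target_r2_range must be increasing within (0, 1)", call. = FALSE)
  }
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  structure(list(
    n_parcels = as.integer(n_parcels), band_names = band_names,
    decay_length = decay_length, weight_smoothness = weight_smoothness,
    noise_profile = noise_profile, noise_sd_range = noise_sd_range,
    target_r2_range = target_r2_range,
    band_modulation = band_modulation, band_noise_sd = band_noise_sd,
    n_subjects = as.integer(n_subjects), subject_noise_sd = subject_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate six band-limited group-average connectivity matrices
#'
#' Each band matrix is built as a distance-decaying baseline
#' `0.5 * exp(-d / decay_length)` plus a band-specific smooth spatial
#' modulation (rank-one product of a smooth map with itself) and symmetric
#' Gaussian noise, clipped to `[-1, 1]`, with a zero diagonal (the package's
#' excluded-diagonal convention).
#'
#' @param geometry Output of [make_geometry()].
#' @param config A [synthetic_config()].
#' @return A `band_fc_set`: named list of six symmetric matrices, in
#'   canonical band order.
#' @export
make_band_fc_set <- function(geometry, config) {
  check_geometry(geometry)
  if (config$decay_length <= 0) stop("decay_length must be positive", call. = FALSE)
  n <- nrow(geometry)
  d <- geometry_dist(geometry)
  base <- 0.5 * exp(-d / config$decay_length)
  with_seed_(config$seed, {
    mats <- lapply(seq_along(config$band_names), function(b) {
      g <- smooth_sphere_map(geometry, config$weight_smoothness)
      g <- g / max(stats::sd(g), 1e-12)
      mod <- config$band_modulation * tcrossprod(g)
      noise <- matrix(stats::rnorm(n * n, sd = config$band_noise_sd), n, n)
      m <- base + mod + symmetrize(noise)
      m <- pmin(pmax(m, -0.99), 0.99)
      diag(m) <- 0
      m
    })
  })
  names(mats) <- config$band_names
  structure(mats, class = "band_fc_set")
}

#' @keywords internal
#' @noRd
check_band_set <- function(bands) {
  if (length(bands) != 6) stop("a band FC set must contain 6 matrices", call. = FALSE)
  n <- unique(vapply(bands, nrow, integer(1)))
  if (length(n) != 1) stop("band matrices must share one parcellation", call. = FALSE)
  invisible(bands)
}

#' Build a haemodynamic matrix as a known region-wise mixture of band matrices
#'
#' Generates the planted ground truth for the regional multilinear model: the
#' i-th row of the haemodynamic matrix is a linear combination of the i-th
#' rows of the six band matrices with region-specific weights that vary
#' smoothly along a synthetic unimodal-to-transmodal hierarchy. The row-wise
#' signal is symmetrized by averaging, so entry (i, j) mixes the weight
#' profiles of both endpoint regions; symmetric Gaussian noise with entry
#' variance `sd_i * sd_j` (regional scales constant or graded along the
#' hierarchy) is then added. The analytic target variance-explained per
#' region is `target_r2[i] = ev_i / (v_i + nv_i)`, where `v_i` is the
#' variance of the noiseless symmetrized signal row, `ev_i` the share of it
#' explainable by the band profiles (computed by a deterministic noise-free
#' fit, since region-varying weights take the symmetrized mixture slightly
#' outside the regional model class), and `nv_i = sd_i * mean(sd_-i)` the
#' mean noise variance of row i.
#'
#' @param band_fc_set Output of [make_band_fc_set()].
#' @param geometry The matching geometry.
#' @param config A [synthetic_config()].
#' @param weights Optional `n_parcels x 6` matrix overriding the generated
#'   mixing weights (e.g. to plant band dominance patterns).
#' @return A list with `haemo` (symmetric matrix, zero diagonal) and `truth`,
#'   a `ground_truth` list holding `weights`, `intercept`, `noise_sd`,
#'   `hierarchy`, and `target_r2`.
#' @export
make_crossmodal_truth <- function(band_fc_set, geometry, config, weights = NULL) {
  check_band_set(band_fc_set)
  check_geometry(geometry)
  n <- nrow(geometry)
  if (nrow(band_fc_set[[1]]) != n) {
    stop("band matrices and geometry disagree on parcellation size", call. = FALSE)
  }
  with_seed_(config$seed + 1L, {
    # rank-uniformized smooth map: spatially smooth with a uniform marginal,
    # so hierarchy positions (and the graded noise) spread evenly over [0, 1]
    hierarchy <- (rank(smooth_sphere_map(geometry, config$weight_smoothness)) - 0.5) / n
    if (is.null(weights)) {
      # band profiles along the hierarchy: alpha/beta carry most signal near
      # the unimodal end, slower rhythms gain weight toward the transmodal end
      base <- c(delta = 0.10, theta = 0.15, alpha = 0.35, beta = 0.45,
                lgamma = 0.10, hgamma = 0.05)
      slope <- c(delta = 0.15, theta = 0.15, alpha = -0.20, beta = -0.25,
                 lgamma = 0.05, hgamma = 0.05)
      weights <- outer(hierarchy, slope) + rep(base, each = n)
    } else {
      if (!is.matrix(weights) || nrow(weights) != n || ncol(weights) != 6) {
        stop("weights must be an n_parcels x 6 matrix", call. = FALSE)
      }
    }
    colnames(weights) <- names(band_fc_set)
    intercept <- 0.1
    # row-wise signal, then symmetrized: S_ij = sum_b (w_ib + w_jb)/2 * B_b,ij
    signal <- matrix(0, n, n)
    for (b in seq_along(band_fc_set)) {
      wb <- weights[, b]
      signal <- signal + (outer(wb, rep(1, n)) + outer(rep(1, n), wb)) / 2 *
        band_fc_set[[b]]
    }
    signal <- signal + intercept
    diag(signal) <- 0
    v <- vapply(seq_len(n), function(i) stats::var(signal[i, -i]), numeric(1))
    # variance of the noiseless signal row explained by the band profiles:
    # with region-varying weights the symmetrized mixture is not exactly in
    # the regional model class, so the explainable share is computed by a
    # deterministic fit on the noise-free signal
    ev <- vapply(seq_len(n), function(i) {
      fit <- ols_fit(cbind(1, band_profile_matrix(band_fc_set, i)),
                     regional_profile(signal, i))
      v[i] * max(fit$r2, 0)
    }, numeric(1))
    noise_sd <- switch(config$noise_profile,
      graded = {
        # expected variance explained declines linearly along the hierarchy;
        # with entry variance sd_i * sd_j, row i's mean noise variance is
        # nv_i = sd_i * mean(sd_-i), so the per-region scales solving
        # nv_i = ev_i / r_i - v_i follow from a fast fixed point
        r <- config$target_r2_range[2] -
          diff(config$target_r2_range) * hierarchy
        nv_target <- pmax(ev / r - v, 0)
        s <- sqrt(nv_target)
        if (mean(nv_target) > 0) {
          for (it in 1:50) s <- nv_target * (n - 1) / (sum(s) - s)
        }
        s
      },
      constant = rep(mean(config$noise_sd_range), n)
    )
    # symmetric noise field with entry variance sd_i * sd_j: multiplicative
    # coupling lets clean regions stay clean next to noisy ones, which the
    # additive row-averaging scheme cannot do
    z <- matrix(stats::rnorm(n * n), n, n)
    z <- (z + t(z)) / sqrt(2)
    noise <- tcrossprod(sqrt(noise_sd)) * z
    haemo <- signal + noise
    diag(haemo) <- 0
  })
  nv <- vapply(seq_len(n), function(i) {
    noise_sd[i] * mean(noise_sd[-i])
  }, numeric(1))
  target_r2 <- ifelse(v + nv > 0, ev / (v + nv), 0)
  truth <- structure(list(
    weights = weights, intercept = intercept, noise_sd = noise_sd,
    hierarchy = hierarchy, target_r2 = target_r2
  ), class = "ground_truth")
  list(haemo = haemo, truth = truth)
}

#' Generate a per-subject ensemble around group-average matrices
#'
#' Each subject's matrix is the group matrix plus independent symmetric
#' Gaussian noise of scale `subject_noise_sd`, so the ensemble mean converges
#' to the group matrix as subjects accumulate.
#'
#' @param haemo Group-average haemodynamic matrix.
#' @param band_fc_set Group-average `band_fc_set`.
#' @param n_subjects Integer >= 2.
#' @param subject_noise_sd Non-negative noise scale.
#' @param seed Integer seed.
#' @return A list of `n_subjects` elements, each with `haemo` and `bands`.
#' @export
make_subject_ensemble <- function(haemo, band_fc_set, n_subjects,
                                  subject_noise_sd, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  check_band_set(band_fc_set)
  n <- nrow(haemo)
  perturb <- function(m) {
    e <- symmetrize(matrix(stats::rnorm(n * n, sd = subject_noise_sd), n, n))
    diag(e) <- 0
    m + e
  }
  with_seed_(seed, {
    lapply(seq_len(n_subjects), function(s) {
      bands <- lapply(band_fc_set, perturb)
      class(bands) <- "band_fc_set"
      list(haemo = perturb(haemo), bands = bands)
    })
  })
}

#' Generate microarchitectural context data tied to an anchor map
#'
#' Produces the three context inputs with planted structure: (1) laminar
#' staining-intensity profiles over `n_depths` cortical depths whose
#' correlation with `anchor_map` peaks at `depth_peak`; (2) a multi-donor
#' gene expression panel with tunable cross-donor consistency and one
#' designated gene whose latent pattern has a planted correlation with the
#' anchor map; (3) a sparse non-negative structural connectivity matrix with
#' distance decay.
#'
#' @param geometry Parcel geometry.
#' @param anchor_map Finite numeric vector, one value per parcel.
#' @param n_depths Number of intracortical depth surfaces (default 50).
#' @param depth_peak Depth index at which |correlation| with the anchor peaks.
#' @param depth_width Width (in depths) of the correlation peak.
#' @param n_genes Number of genes in the panel (designated gene included).
#' @param n_donors Number of synthetic donors (>= 2).
#' @param donor_consistency Cross-donor pattern consistency in `[0, 1]`;
#'   1 makes all donors identical.
#' @param designated_gene Name given to the anchored gene.
#' @param planted_cor Latent (Gaussian-scale) correlation between the
#'   designated gene's pattern and the anchor map.
#' @param sc_decay_length Distance constant of the structural decay.
#' @param seed Integer seed.
#' @return A list with `depth_profiles` (parcel x depth matrix),
#'   `expression` (an `expression_panel`: named list of donor
#'   parcel x gene matrices), and `structural` (matrix).
#' @export
make_context_maps <- function(geometry, anchor_map, n_depths = 50L,
                              depth_peak = 15L, depth_width = 8,
                              n_genes = 30L, n_donors = 6L,
                              donor_consistency = 0.8,
                              designated_gene = "ANCHOR_GENE",
                              planted_cor = -0.6,
                              sc_decay_length = 0.75, seed = 1L) {
  check_geometry(geometry)
  n <- nrow(geometry)
  if (length(anchor_map) != n) {
    stop("anchor_map length must equal the number of parcels", call. = FALSE)
  }
  if (any(!is.finite(anchor_map))) {
    stop("anchor_map must be finite", call. = FALSE)
  }
  if (n_donors < 2) stop("need at least 2 donors", call. = FALSE)
  stopifnot(donor_consistency >= 0, donor_consistency <= 1,
            abs(planted_cor) <= 1)
  # rank-normalized anchor: planted correlations are on the Gaussian scale
  za <- stats::qnorm((rank(anchor_map) - 0.5) / n)
  za <- za / stats::sd(za)
  with_seed_(seed, {
    # depth profiles share one nuisance map so the |correlation| profile over
    # depth follows the loading curve deterministically
    eta <- smooth_sphere_map(geometry, 0.5)
    eta <- (eta - mean(eta)) / stats::sd(eta)
    a <- 0.95 * exp(-((seq_len(n_depths) - depth_peak)^2) / (2 * depth_width^2))
    profiles <- sapply(seq_len(n_depths), function(d) {
      a[d] * za + sqrt(1 - a[d]^2) * eta + stats::rnorm(n, sd = 0.01)
    })
    rownames(profiles) <- geometry$parcel
    colnames(profiles) <- paste0("depth", seq_len(n_depths))

    gene_names <- c(designated_gene,
                    sprintf("GENE%03d", seq_len(n_genes - 1)))
    latents <- sapply(seq_len(n_genes), function(g) {
      m <- smooth_sphere_map(geometry, 0.5)
      (m - mean(m)) / stats::sd(m)
    })
    latents[, 1] <- planted_cor * za +
      sqrt(1 - planted_cor^2) * latents[, 1]
    donors <- lapply(seq_len(n_donors), function(k) {
      noise <- matrix(stats::rnorm(n * n_genes), n, n_genes)
      b <- donor_consistency * latents +
        sqrt(1 - donor_consistency^2) * noise
      dimnames(b) <- list(geometry$parcel, gene_names)
      b
    })
    names(donors) <- paste0("donor", seq_len(n_donors))
    panel <- structure(donors, class = "expression_panel")

    d <- geometry_dist(geometry)
    p_edge <- exp(-d / sc_decay_length)
    u <- matrix(stats::runif(n * n), n, n)
    u[lower.tri(u)] <- t(u)[lower.tri(u)]   # one draw per pair
    sc <- ifelse(u < p_edge & p_edge > 0.02, p_edge, 0)
    diag(sc) <- 0
  })
  list(depth_profiles = profiles, expression = panel, structural = sc)
}

#' Generate band-limited time series with planted pairwise coupling
#'
#' Builds narrowband signals in one carrier band. Regions listed in
#' `envelope_pairs` share a common slow amplitude envelope riding on
#' independent constant-amplitude carriers (detectable by leakage-corrected
#' amplitude envelope correlation); regions listed in `locking_pairs` are
#' phase-shifted copies of one narrowband noise signal (phase-locking value
#' near 1). All other regions are independent narrowband noise.
#'
#' @param n_regions Number of regions.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz; must exceed twice the highest canonical
#'   band edge (180 Hz).
#' @param band Carrier band (`frequency_band` or canonical name).
#' @param envelope_pairs,locking_pairs Lists of length-2 integer vectors.
#' @param seed Integer seed.
#' @return A `parcel_ts` list: `values` (region x sample matrix), `fs`,
#'   `labels`.
#' @export
make_band_timeseries <- function(n_regions, duration_s, fs, band = "alpha",
                                 envelope_pairs = list(),
                                 locking_pairs = list(), seed = 1L) {
  if (fs <= 2 * 90) {
    stop("sampling rate must exceed twice the highest band edge (fs > 180 Hz)",
         call. = FALSE)
  }
  band <- as_band(band)
  n_samp <- round(duration_s * fs)
  t <- seq_len(n_samp) / fs
  filt <- signal::butter(4, c(band$lo, band$hi) / (fs / 2), type = "pass")
  narrowband_noise <- function() {
    x <- signal::filtfilt(filt, stats::rnorm(n_samp))
    x / stats::sd(x)
  }
  slow_envelope <- function() {
    lp <- signal::butter(2, 0.5 / (fs / 2), type = "low")
    s <- signal::filtfilt(lp, stats::rnorm(n_samp))
    s <- s / max(stats::sd(s), 1e-12)
    1 + 0.8 * tanh(s)
  }
  with_seed_(seed, {
    values <- t(sapply(seq_len(n_regions), function(i) narrowband_noise()))
    for (pr in envelope_pairs) {
      e <- slow_envelope()
      f1 <- stats::runif(1, band$lo + 0.2 * (band$hi - band$lo),
                         band$hi - 0.2 * (band$hi - band$lo))
      f2 <- stats::runif(1, band$lo + 0.2 * (band$hi - band$lo),
                         band$hi - 0.2 * (band$hi - band$lo))
      values[pr[1], ] <- e * cos(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi))
      values[pr[2], ] <- e * cos(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi))
    }
    for (pr in locking_pairs) {
      x <- narrowband_noise()
      phi <- stats::runif(1, pi / 6, pi / 2)
      values[pr[1], ] <- x
      values[pr[2], ] <- Re(analytic_signal(x) * exp(1i * phi))
    }
  })
  structure(list(values = values, fs = fs,
                 labels = paste0("region", seq_len(n_regions))),
            class = "parcel_ts")
}
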