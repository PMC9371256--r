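# Shared fixtures: small seeded synthetic instances used across test files.

tiny_instance <- function(n_parcels = 60, seed = 101,
                          noise_profile = "graded", weights = NULL, ...) {
  cfg <- synthetic_config(n_parcels = n_parcels, seed = seed,
                          noise_profile = noise_profile, ...)
  geometry <- make_geometry(n_parcels, seed = seed)
  bands <- make_band_fc_set(geometry, cfg)
  truthed <- make_crossmodal_truth(bands, geometry, cfg, weights = weights)
  list(config = cfg, geometry = geometry, bands = bands,
       haemo = truthed$haemo, truth = truthed$truth)
}

# noiseless instance with constant weights: the regional model class holds
# exactly, so fits must recover the planted coefficients to round-off
noiseless_instance <- function(n_parcels = 60, seed = 202,
                               w = c(0.2, 0.1, 0.3, 0.4, 0.1, 0.05)) {
  weights <- matrix(rep(w, each = n_parcels), n_parcels)
  tiny_instance(n_parcels, seed, noise_profile = "constant",
                noise_sd_range = c(0, 0), weights = weights)
}

# independent brute-force least squares via explicit normal equations
normal_equations_fit <- function(x, y) {
  xx <- cbind(1, x)
  solve(t(xx) %*% xx, t(xx) %*% y)[, 1]
}

# Exhaustive reference implementation of general dominance: subset fits via
# lm(), incremental gains averaged within then across subset sizes, straight
# from the definition.
brute_force_dominance <- function(y, x, metric = "adjusted") {
  p <- ncol(x)
  fit_sub <- function(idx) {
    if (length(idx) == 0) return(0)
    s <- summary(stats::lm(y ~ x[, idx, drop = FALSE]))
    if (metric == "adjusted") s$adj.r.squared else s$r.squared
  }
  total <- numeric(p)
  for (k in seq_len(p)) {
    by_size <- numeric(p)
    for (s in 0:(p - 1)) {
      others <- setdiff(seq_len(p), k)
      subsets <- if (s == 0) {
        list(integer(0))
      } else if (length(others) == 1) {
        list(others)
      } else {
        asplit(utils::combn(others, s), 2)
      }
      gains <- vapply(subsets, function(sub) {
        fit_sub(c(sub, k)) - fit_sub(sub)
      }, numeric(1))
      by_size[s + 1] <- mean(gains)
    }
    total[k] <- mean(by_size)
  }
  total
}
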