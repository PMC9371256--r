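test_that("geometry lies on the unit sphere, mirrored across the midline", {
  g <- make_geometry(10, seed = 1)
  norms <- sqrt(g$x^2 + g$y^2 + g$z^2)
  expect_true(all(abs(norms - 1) < 1e-12))
  left <- g[g$hemi == "L", c("x", "y", "z")]
  right <- g[g$hemi == "R", c("x", "y", "z")]
  expect_equal(as.matrix(left) * rep(c(-1, 1, 1), each = nrow(left)),
               as.matrix(right), ignore_attr = TRUE)
  expect_identical(make_geometry(10, seed = 1), g)
  expect_false(identical(make_geometry(10, seed = 2), g))
  expect_error(make_geometry(11, seed = 1), "even")
  expect_error(make_geometry(8, seed = 1), "even")
})

test_that("band FC matrices are symmetric, bounded, and distance-decaying", {
  inst <- tiny_instance(40, seed = 3, decay_length = 0.3)
  d <- as.matrix(dist(as.matrix(inst$geometry[, c("x", "y", "z")])))
  for (m in inst$bands) {
    expect_identical(m, t(m))
    expect_true(all(abs(m) <= 1))
    expect_true(all(is.finite(m)))
    expect_true(all(diag(m) == 0))
  }
  m <- inst$bands[[1]]
  off <- row(m) != col(m)
  near <- d <= quantile(d[off], 0.1) & off
  far <- d >= quantile(d[off], 0.9) & off
  expect_gt(mean(m[near]), mean(m[far]))
})

test_that("with infinite decay and no modulation, FC is flat in distance", {
  diffs <- ses <- numeric(200)
  for (s in seq_len(200)) {
    cfg <- synthetic_config(n_parcels = 20, seed = s, decay_length = 1e6,
                            band_modulation = 0, band_noise_sd = 0.05)
    g <- make_geometry(20, seed = s)
    m <- make_band_fc_set(g, cfg)[[1]]
    d <- as.matrix(dist(as.matrix(g[, c("x", "y", "z")])))
    off <- row(m) != col(m)
    near <- m[d <= quantile(d[off], 0.1) & off]
    far <- m[d >= quantile(d[off], 0.9) & off]
    diffs[s] <- mean(near) - mean(far)
    ses[s] <- sqrt(var(near) / length(near) + var(far) / length(far))
  }
  expect_lt(abs(mean(diffs)), 2 * mean(ses) / sqrt(200))
})

test_that("noiseless constant-weight mixture is exactly identifiable", {
  w <- c(0.2, 0.1, 0.3, 0.4, 0.1, 0.05)
  inst <- noiseless_instance(60, seed = 5, w = w)
  fit <- fit_regional_model(inst$haemo, inst$bands, 7)
  expect_lt(max(abs(fit$coefficients[-1] - w)), 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_true(all(inst$truth$target_r2 >= 0 & inst$truth$target_r2 <= 1))
})

test_that("graded noise makes target R2 decline monotonically along the hierarchy", {
  inst <- tiny_instance(200, seed = 7)
  expect_lte(cor(inst$truth$target_r2, inst$truth$hierarchy,
                 method = "spearman"), -0.9)
})

test_that("zero weights with noise give fitted adjusted-R2 near zero", {
  adj <- unlist(lapply(1:5, function(s) {
    inst <- tiny_instance(100, seed = 300 + s, noise_profile = "constant",
                          noise_sd_range = c(0.1, 0.1),
                          weights = matrix(0, 100, 6))
    fit_all_regions(inst$haemo, inst$bands)$adj_r2
  }))
  expect_lt(abs(mean(adj)), 0.05)
})

test_that("subject ensembles are centred on the group matrices", {
  inst <- tiny_instance(20, seed = 9)
  subs0 <- make_subject_ensemble(inst$haemo, inst$bands, 3, 0, seed = 1)
  for (s in subs0) expect_equal(s$haemo, inst$haemo)
  expect_identical(make_subject_ensemble(inst$haemo, inst$bands, 4, 0.1, seed = 2),
                   make_subject_ensemble(inst$haemo, inst$bands, 4, 0.1, seed = 2))
  subs <- make_subject_ensemble(inst$haemo, inst$bands, 500, 0.2, seed = 3)
  avg <- Reduce(`+`, lapply(subs, `[[`, "haemo")) / 500
  expect_lt(max(abs(avg - inst$haemo)), 5 * 0.2 / sqrt(500))
  expect_error(make_subject_ensemble(inst$haemo, inst$bands, 1, 0.1), ">= 2")
})

test_that("context maps plant the depth peak, donor consistency, and sparsity", {
  g <- make_geometry(100, seed = 12)
  anchor <- smooth_sphere_map(g, 0.5, seed = 13)
  cm <- make_context_maps(g, anchor, depth_peak = 20, seed = 14)
  rs <- vapply(seq_len(ncol(cm$depth_profiles)), function(d) {
    abs(cor(cm$depth_profiles[, d], anchor, method = "spearman"))
  }, numeric(1))
  expect_identical(which.max(rs), 20L)
  expect_identical(ncol(cm$depth_profiles), 50L)

  cm1 <- make_context_maps(g, anchor, donor_consistency = 1, seed = 14)
  for (gene in colnames(cm1$expression[[1]])[1:5]) {
    expect_equal(differential_stability(cm1$expression, gene), 1,
                 tolerance = 1e-12)
  }

  off <- row(cm$structural) != col(cm$structural)
  expect_true(any(cm$structural[off] == 0))
  expect_true(all(cm$structural >= 0))
  expect_identical(cm$structural, t(cm$structural))
  expect_error(make_context_maps(g, c(anchor[-1], NA)), "finite")
})

test_that("band time series plant phase locking and envelope coupling", {
  ts <- make_band_timeseries(6, duration_s = 120, fs = 250, band = "alpha",
                             envelope_pairs = list(c(1, 2)),
                             locking_pairs = list(c(3, 4)), seed = 21)
  p <- plv(ts, "alpha")
  expect_gte(p[3, 4], 0.99)
  expect_lt(p[5, 6], 0.1)
  a <- aec(ts, "alpha", leakage_correction = TRUE)
  expect_gte(a[1, 2], 0.7)
  expect_identical(make_band_timeseries(3, 20, 250, seed = 5)$values,
                   make_band_timeseries(3, 20, 250, seed = 5)$values)
  expect_error(make_band_timeseries(4, 10, fs = 150), "180")
})
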