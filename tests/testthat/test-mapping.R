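test_that("regional profiles drop the diagonal and keep region order", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, byrow = TRUE)
  expect_equal(regional_profile(m, 1), c(1, 2), ignore_attr = TRUE)
  set.seed(81)
  r <- matrix(rnorm(36), 6)
  for (i in 1:6) {
    prof <- regional_profile(r, i)
    expect_length(prof, 5)
    expect_equal(prof, r[i, setdiff(1:6, i)], ignore_attr = TRUE)
  }
  expect_error(regional_profile(r, 7), "range")
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(1, 100, 6), 1)
  expect_equal(adjusted_r2(0.37, 50, 0), 0.37)
  expect_equal(adjusted_r2(0.5, 399, 6), 0.492347, tolerance = 1e-6)
  expect_error(adjusted_r2(0.5, 7, 6), "n_obs")
})

test_that("regional fits match an independent normal-equations oracle", {
  inst <- tiny_instance(10, seed = 91)
  for (i in c(1, 5, 10)) {
    fit <- fit_regional_model(inst$haemo, inst$bands, i)
    x <- sapply(inst$bands, function(m) m[i, -i])
    oracle <- normal_equations_fit(x, inst$haemo[i, -i])
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
    resid <- inst$haemo[i, -i] - fit$predicted_profile
    expect_lt(max(abs(crossprod(cbind(1, x), resid))), 1e-8)
    expect_lte(fit$adj_r2, fit$r2)
  }
})

test_that("a haemodynamic row equal to one band row is recovered exactly", {
  inst <- tiny_instance(30, seed = 92)
  haemo <- inst$bands[["beta"]]
  fit <- fit_regional_model(haemo, inst$bands, 4)
  expect_lt(max(abs(fit$coefficients - c(0, 0, 0, 0, 1, 0, 0))), 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("the correspondence map has length N and is permutation equivariant", {
  inst <- tiny_instance(20, seed = 93)
  fits <- fit_all_regions(inst$haemo, inst$bands)
  expect_length(fits$adj_r2, 20)
  perm <- sample(20)
  bands_p <- lapply(inst$bands, function(m) m[perm, perm])
  class(bands_p) <- "band_fc_set"
  fits_p <- fit_all_regions(inst$haemo[perm, perm], bands_p)
  expect_equal(fits_p$adj_r2, fits$adj_r2[perm], tolerance = 1e-10)
})

test_that("the global model fits the upper triangle with the right count", {
  inst <- tiny_instance(20, seed = 94)
  fit <- fit_global_model(inst$haemo, inst$bands)
  expect_length(fit$predicted, 20 * 19 / 2)
  ut <- upper.tri(inst$haemo)
  x <- sapply(inst$bands, function(m) m[ut])
  oracle <- normal_equations_fit(x, inst$haemo[ut])
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)

  nl <- noiseless_instance(30, seed = 95)
  expect_equal(fit_global_model(nl$haemo, nl$bands)$adj_r2, 1,
               tolerance = 1e-10)
})

test_that("single-band fits are nested within the full model", {
  inst <- tiny_instance(30, seed = 96)
  full <- fit_all_regions(inst$haemo, inst$bands)
  single <- fit_band_specific_models(inst$haemo, inst$bands)
  expect_identical(dim(single$adj_r2), c(30L, 6L))
  for (i in 1:30) {
    expect_gte(full$r2[i] + 1e-12, max(single$r2[i, ]))
  }
})

test_that("a single generating band makes its map match the full model", {
  # 400 parcels: at n = 399 observations the five inert predictors absorb
  # too little noise to separate the nested fits
  w <- c(0, 0, 0, 1, 0, 0)  # beta as the sole generator
  inst <- tiny_instance(400, seed = 97, noise_profile = "constant",
                        noise_sd_range = c(0.1, 0.1),
                        weights = matrix(rep(w, each = 400), 400))
  full <- fit_all_regions(inst$haemo, inst$bands)
  single <- fit_band_specific_models(inst$haemo, inst$bands)
  expect_lt(max(abs(single$adj_r2[, "beta"] - full$adj_r2)), 0.02)
})

test_that("rank-deficient predictors fall back to a minimum-norm fit", {
  inst <- tiny_instance(20, seed = 98)
  bands <- inst$bands
  bands[["theta"]] <- bands[["delta"]]  # exact collinearity
  class(bands) <- "band_fc_set"
  expect_warning(fit <- fit_regional_model(inst$haemo, bands, 1),
                 "rank-deficient")
  expect_true(all(is.finite(fit$coefficients)))
})
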