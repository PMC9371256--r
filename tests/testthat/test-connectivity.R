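test_that("bandpass has unit passband gain and attenuates out-of-band tones", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  tone <- sin(2 * pi * 10 * t)
  ts <- parcel_ts(rbind(tone, tone), fs)
  alpha_out <- bandpass(ts, "alpha")$values[1, ]
  mid <- seq(2 * fs, 8 * fs)  # avoid filter edge transients
  amp <- 2 * sqrt(mean(alpha_out[mid]^2)) / sqrt(2)
  expect_gte(amp, 0.89)
  expect_lte(amp, 1.12)
  delta_out <- bandpass(ts, "delta")$values[1, mid]
  expect_lt(sqrt(mean(delta_out^2)), 0.1)
  zero <- parcel_ts(matrix(0, 2, 1000), fs)
  expect_lt(max(abs(bandpass(zero, "alpha")$values)), 1e-12)
  expect_error(bandpass(parcel_ts(matrix(rnorm(200), 2), fs = 100), "hgamma"),
               "Nyquist")
})

test_that("orthogonalization removes exactly the zero-lag projection", {
  set.seed(31)
  x <- rnorm(1000)
  expect_lt(sqrt(mean(orthogonalize_pair(x, 3 * x)^2)), 1e-10)
  y <- rnorm(1000)
  y_orth <- y - sum(x * y) / sum(x * x) * x  # brute-force inner products
  expect_equal(orthogonalize_pair(x, y), y_orth, tolerance = 1e-12)
  expect_lt(abs(sum(orthogonalize_pair(x, y) * x)), 1e-10 * sqrt(sum(x^2)))
  expect_identical(orthogonalize_pair(numeric(1000), y), y)
  y_perp <- y_orth
  expect_equal(orthogonalize_pair(x, y_perp), y_perp, tolerance = 1e-12)
})

test_that("leakage-corrected AEC suppresses duplicated signals", {
  for (s in 1:5) {
    ts <- make_band_timeseries(2, 60, 250, band = "alpha", seed = 400 + s)
    dup <- parcel_ts(rbind(ts$values[1, ], ts$values[1, ]), 250)
    msgs <- capture_warnings(a <- aec(dup, "alpha", leakage_correction = TRUE))
    expect_match(msgs, "identically zero", all = TRUE)
    expect_gt(length(msgs), 0)
    expect_lt(abs(a[1, 2]), 0.05)
  }
})

test_that("AEC output is symmetric and correction blocks zero-lag leakage", {
  ts <- make_band_timeseries(4, 120, 250, band = "alpha",
                             envelope_pairs = list(c(1, 2)), seed = 41)
  a <- aec(ts, "alpha")
  expect_identical(a, t(a))
  # an independent pair with one signal leaking into the other at zero lag:
  # corrected AEC barely moves while uncorrected AEC is inflated
  indep <- make_band_timeseries(2, 120, 250, band = "alpha", seed = 77)
  a0 <- aec(indep, "alpha")
  leaked <- indep
  leaked$values[2, ] <- leaked$values[2, ] + 0.4 * leaked$values[1, ]
  a1 <- aec(leaked, "alpha")
  a1_raw <- aec(leaked, "alpha", leakage_correction = FALSE)
  expect_lt(abs(a1[1, 2] - a0[1, 2]), 0.05)
  expect_gt(a1_raw[1, 2] - a1[1, 2], 0)
})

test_that("PLV is 1 for locked pairs, bounded, and amplitude invariant", {
  ts <- make_band_timeseries(4, 120, 250, band = "alpha",
                             locking_pairs = list(c(1, 2)), seed = 51)
  p <- plv(ts, "alpha")
  expect_equal(p[1, 2], 1, tolerance = 1e-4)
  expect_true(all(p >= 0 & p <= 1))
  scaled <- ts
  scaled$values[1, ] <- 7.3 * scaled$values[1, ]
  expect_equal(plv(scaled, "alpha"), p, tolerance = 1e-6)
  bad <- ts
  bad$values[3, ] <- 1
  expect_error(plv(bad, "alpha"), "constant")
})

test_that("haemodynamic FC matches a brute-force correlation oracle", {
  set.seed(61)
  x <- rnorm(100)
  ts <- parcel_ts(rbind(x, 2 * x + 1, -x, rnorm(100), rnorm(100)), fs = 1)
  fc <- haemodynamic_fc(ts)
  expect_equal(fc[1, 2], 1, tolerance = 1e-12)
  expect_equal(fc[1, 3], -1, tolerance = 1e-12)
  # independent covariance-based oracle
  v <- ts$values
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    if (i != j) {
      oracle[i, j] <- mean((v[i, ] - mean(v[i, ])) * (v[j, ] - mean(v[j, ]))) /
        (sd(v[i, ]) * sd(v[j, ])) * 100 / 99
    }
  }
  expect_lt(max(abs(fc - oracle)), 1e-10)
  bad <- parcel_ts(rbind(x, rep(1, 100)), fs = 1, labels = c("a", "b"))
  expect_error(haemodynamic_fc(bad), "b")
})

test_that("source SNR follows the dipole gain formula", {
  expect_equal(source_snr(10, gains = 1, noise_vars = 100), 0)
  expect_equal(source_snr(10, gains = c(1, 1), noise_vars = c(1, 1)), 20)
  set.seed(71)
  gains <- runif(30); nv <- runif(30, 0.5, 2)
  expect_equal(source_snr(20, gains, nv) - source_snr(10, gains, nv),
               20 * log10(2), tolerance = 1e-12)
  expect_error(source_snr(10, 1, 0), "positive")
})
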