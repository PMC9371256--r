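#' Off-diagonal connectivity profile of one region
#'
#' @param matrix Square connectivity matrix.
#' @param i Region index (1-based).
#' @return Length `N - 1` vector: row `i` with the diagonal entry removed,
#'   original region order preserved.
#' @export
regional_profile <- function(matrix, i) {
  n <- nrow(matrix)
  if (i < 1 || i > n) stop("region index out of range", call. = FALSE)
  matrix[i, -i]
}

#' Adjusted coefficient of determination
#'
#' Ezekiel's formula `1 - (1 - r2) (n - 1) / (n - p - 1)`. With zero
#' predictors the penalty vanishes and `r2` is returned unchanged.
#'
#' @param r2 Unadjusted coefficient of determination.
#' @param n_obs Number of observations.
#' @param n_predictors Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n_obs, n_predictors) {
  if (n_predictors == 0) return(r2)
  if (n_obs <= n_predictors + 1) {
    stop("need n_obs > n_predictors + 1", call. = FALSE)
  }
  1 - (1 - r2) * (n_obs - 1) / (n_obs - n_predictors - 1)
}

#' @keywords internal
#' @noRd
ols_fit <- function(x, y) {
  # x includes the intercept column; returns coefficients, fitted, r2
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient predictor matrix; minimum-norm solution used")
    coef <- as.vector(MASS::ginv(x) %*% y)
  } else {
    coef <- qr.coef(qx, y)
  }
  fitted <- as.vector(x %*% coef)
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - fitted)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(coef = coef, fitted = fitted, r2 = r2)
}

#' @keywords internal
#' @noRd
band_profile_matrix <- function(bands, i) {
  sapply(bands, function(m) regional_profile(m, i))
}

#' Fit the regional multilinear cross-modal model for one region
#'
#' Ordinary least squares of the region's haemodynamic connectivity profile
#' (its row of the haemodynamic matrix, self-connection excluded) on the six
#' corresponding band-limited electromagnetic profiles plus an intercept:
#' `FC_i = b1 FC(delta)_i + ... + b6 FC(hgamma)_i + b0`. Goodness of fit is
#' the adjusted R-squared with `n = N - 1` observations and `p = 6`
#' predictors.
#'
#' @param haemo Haemodynamic connectivity matrix.
#' @param bands A `band_fc_set` on the same parcellation.
#' @param i Region index.
#' @return A `regional_fit` list: `region`, `coefficients` (b0 then the six
#'   band slopes), `r2`, `adj_r2`, `predicted_profile`.
#' @export
fit_regional_model <- function(haemo, bands, i) {
  check_band_set(bands)
  n <- nrow(haemo)
  if (nrow(bands[[1]]) != n) {
    stop("haemodynamic and band matrices disagree on parcellation size",
         call. = FALSE)
  }
  if (n - 1 <= 7) stop("need N - 1 > 7 observations per regional fit", call. = FALSE)
  y <- regional_profile(haemo, i)
  xb <- band_profile_matrix(bands, i)
  fit <- ols_fit(cbind(intercept = 1, xb), y)
  coef <- fit$coef
  names(coef) <- c("b0", paste0("b", seq_len(ncol(xb))))
  structure(list(
    region = i, coefficients = coef, r2 = fit$r2,
    adj_r2 = adjusted_r2(fit$r2, n - 1, ncol(xb)),
    predicted_profile = fit$fitted
  ), class = "regional_fit")
}

#' Fit the regional model for every region
#'
#' @inheritParams fit_regional_model
#' @return A `regional_fit_set` list: `fits` (per-region `regional_fit`),
#'   `adj_r2` (the cross-modal correspondence map, length N), `r2`.
#' @export
fit_all_regions <- function(haemo, bands) {
  n <- nrow(haemo)
  fits <- lapply(seq_len(n), function(i) fit_regional_model(haemo, bands, i))
  structure(list(
    fits = fits,
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    r2 = vapply(fits, `[[`, numeric(1), "r2")
  ), class = "regional_fit_set")
}

#' Fit the single global cross-modal model
#'
#' One least-squares fit of the vectorized upper triangle of the
#' haemodynamic matrix on the upper triangles of the six band matrices,
#' with `N (N - 1) / 2` observations.
#'
#' @inheritParams fit_regional_model
#' @return A `global_fit` list: `coefficients`, `r2`, `adj_r2`, `predicted`.
#' @export
fit_global_model <- function(haemo, bands) {
  check_band_set(bands)
  n <- nrow(haemo)
  if (n < 5) stop("need at least 5 regions", call. = FALSE)
  ut <- upper.tri(haemo)
  y <- haemo[ut]
  xb <- sapply(bands, function(m) m[ut])
  fit <- ols_fit(cbind(intercept = 1, xb), y)
  coef <- fit$coef
  names(coef) <- c("b0", paste0("b", seq_len(ncol(xb))))
  structure(list(
    coefficients = coef, r2 = fit$r2,
    adj_r2 = adjusted_r2(fit$r2, length(y), ncol(xb)),
    predicted = fit$fitted
  ), class = "global_fit")
}

#' Fit single-band regional models
#'
#' For every region and every band, fits the regional model with that band's
#' profile as the sole predictor, yielding six band-specific
#' correspondence maps.
#'
#' @inheritParams fit_regional_model
#' @return A list with `adj_r2` and `r2`, both `N x 6` matrices (regions by
#'   bands, canonical order).
#' @export
fit_band_specific_models <- function(haemo, bands) {
  check_band_set(bands)
  n <- nrow(haemo)
  if (n - 1 <= 2) stop("too few regions", call. = FALSE)
  r2 <- adj <- matrix(NA_real_, n, length(bands),
                      dimnames = list(NULL, names(bands)))
  for (i in seq_len(n)) {
    y <- regional_profile(haemo, i)
    for (b in seq_along(bands)) {
      fit <- ols_fit(cbind(1, regional_profile(bands[[b]], i)), y)
      r2[i, b] <- fit$r2
      adj[i, b] <- adjusted_r2(fit$r2, n - 1, 1)
    }
  }
  list(adj_r2 = adj, r2 = r2)
}
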