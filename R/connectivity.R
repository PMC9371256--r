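#' Parcellated time series container
#'
#' @param values Region x sample numeric matrix, all finite.
#' @param fs Sampling rate in Hz.
#' @param labels Optional region labels.
#' @return A `parcel_ts` list.
#' @export
parcel_ts <- function(values, fs, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(!is.finite(values))) stop("time series contain non-finite samples", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (is.null(labels)) labels <- paste0("region", seq_len(nrow(values)))
  structure(list(values = values, fs = fs, labels = labels), class = "parcel_ts")
}

#' Zero-phase band-pass filter of parcellated time series
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth band-pass
#' filter to every regional time series. Zero-phase filtering preserves the
#' amplitude envelopes and instantaneous phases that the connectivity
#' measures rely on.
#'
#' @param ts A `parcel_ts`.
#' @param band A `frequency_band` or a canonical band name.
#' @return A filtered `parcel_ts`.
#' @export
bandpass <- function(ts, band) {
  band <- as_band(band)
  if (band$hi >= ts$fs / 2) {
    stop(sprintf("band edge %g Hz at or above the Nyquist frequency %g Hz",
                 band$hi, ts$fs / 2), call. = FALSE)
  }
  filt <- signal::butter(4, c(band$lo, band$hi) / (ts$fs / 2), type = "pass")
  out <- t(apply(ts$values, 1, function(x) signal::filtfilt(filt, x)))
  parcel_ts(out, ts$fs, ts$labels)
}

#' Remove the zero-lag component of one signal from another
#'
#' Returns the residual of `y` after least-squares projection onto `x`,
#' i.e. the part of `y` with no instantaneous linear dependence on `x`.
#' This is the leakage-correction primitive used by [aec()].
#'
#' @param x,y Equal-length numeric vectors.
#' @return Numeric vector: `y - (<x,y>/<x,x>) x`; `y` unchanged when `x` is
#'   identically zero.
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  sxx <- sum(x * x)
  if (sxx == 0) return(y)
  y - (sum(x * y) / sxx) * x
}

#' @keywords internal
#' @noRd
edge_trim_idx <- function(n_samp, fs, lo) {
  # discard filter transients: about two cycles of the band's low edge
  n_edge <- min(round(2 * fs / lo), floor((n_samp - 8) / 4))
  n_edge <- max(n_edge, 0)
  (1 + n_edge):(n_samp - n_edge)
}

#' Amplitude envelope correlation with optional leakage correction
#'
#' Band-passes every regional signal, then for each region pair correlates
#' the analytic-signal amplitude envelopes. With `leakage_correction = TRUE`
#' each signal is first orthogonalized with respect to the other (both
#' directions, averaging the two directed correlations), which removes the
#' shared zero-lag component responsible for spatial leakage. Edge samples
#' (two low-edge cycles at each end) are discarded before correlating to
#' suppress filter transients.
#'
#' @param ts A `parcel_ts`.
#' @param band A `frequency_band` or canonical band name.
#' @param leakage_correction Logical; orthogonalize before enveloping.
#' @return A symmetric N x N matrix with zero diagonal.
#' @export
aec <- function(ts, band, leakage_correction = TRUE) {
  band <- as_band(band)
  n_samp <- ncol(ts$values)
  if (n_samp / ts$fs < 10 / band$lo) {
    stop("recording shorter than 10 cycles of the band's low edge", call. = FALSE)
  }
  filtered <- bandpass(ts, band)$values
  n <- nrow(filtered)
  keep <- edge_trim_idx(n_samp, ts$fs, band$lo)
  envelope <- function(x) Mod(analytic_signal(x))[keep]
  env_raw <- t(apply(filtered, 1, envelope))
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (leakage_correction) {
        r_ij <- directed_aec(filtered[i, ], filtered[j, ], env_raw[i, ], keep)
        r_ji <- directed_aec(filtered[j, ], filtered[i, ], env_raw[j, ], keep)
        out[i, j] <- out[j, i] <- mean(c(r_ij, r_ji))
      } else {
        out[i, j] <- out[j, i] <- stats::cor(env_raw[i, ], env_raw[j, ])
      }
    }
  }
  dimnames(out) <- list(ts$labels, ts$labels)
  out
}

#' @keywords internal
#' @noRd
directed_aec <- function(x, y, env_x, keep) {
  resid <- orthogonalize_pair(x, y)
  if (stats::sd(resid) < 1e-12) {
    warning("orthogonalized residual is identically zero; entry set to 0")
    return(0)
  }
  stats::cor(env_x, Mod(analytic_signal(resid))[keep])
}

#' Phase-locking value connectivity
#'
#' Band-passes the signals, extracts instantaneous phases from the analytic
#' signal, and returns for each pair the modulus of the time-averaged unit
#' phasor of the phase difference. Values lie in `[0, 1]`; 1 means a constant
#' phase lag.
#'
#' @inheritParams aec
#' @return A symmetric N x N matrix in `[0, 1]` with zero diagonal.
#' @export
plv <- function(ts, band) {
  band <- as_band(band)
  n_samp <- ncol(ts$values)
  if (n_samp / ts$fs < 10 / band$lo) {
    stop("recording shorter than 10 cycles of the band's low edge", call. = FALSE)
  }
  const <- apply(ts$values, 1, stats::sd) == 0
  if (any(const)) {
    stop("constant signal (undefined phase) in region(s): ",
         paste(which(const), collapse = ", "), call. = FALSE)
  }
  filtered <- bandpass(ts, band)$values
  keep <- edge_trim_idx(n_samp, ts$fs, band$lo)
  phasors <- t(apply(filtered, 1, function(x) {
    z <- analytic_signal(x)[keep]
    z / Mod(z)
  }))
  # |mean_t e^{i(phi_i - phi_j)}| = |(1/T) sum_t z_i conj(z_j)|
  out <- Mod(phasors %*% Conj(t(phasors))) / ncol(phasors)
  diag(out) <- 0
  dimnames(out) <- list(ts$labels, ts$labels)
  out
}

#' Haemodynamic functional connectivity (Pearson correlation)
#'
#' @param ts A `parcel_ts` of regional haemodynamic signals.
#' @return Symmetric correlation matrix with zero diagonal.
#' @export
haemodynamic_fc <- function(ts) {
  if (ncol(ts$values) < 3) stop("need at least 3 samples", call. = FALSE)
  const <- apply(ts$values, 1, stats::sd) == 0
  if (any(const)) {
    stop("constant time series in region(s): ",
         paste(ts$labels[const], collapse = ", "), call. = FALSE)
  }
  out <- stats::cor(t(ts$values))
  diag(out) <- 0
  dimnames(out) <- list(ts$labels, ts$labels)
  out
}

#' Source-level signal-to-noise ratio in decibels
#'
#' Computes `10 log10( (a^2 / N) * sum_k b_k^2 / s_k^2 )` for a dipolar
#' source of amplitude `a` (nAm) seen by `N` sensors with unit-amplitude
#' forward gains `gains` and per-sensor noise variances `noise_vars`.
#'
#' @param a Source amplitude (nAm); a typical cortical dipole is 10 nAm.
#' @param gains Per-sensor forward-model signal for a unit-amplitude source.
#' @param noise_vars Per-sensor noise variances, all positive.
#' @return SNR in dB.
#' @examples
#' source_snr(10, gains = 1, noise_vars = 100) # 0 dB
#' @export
source_snr <- function(a, gains, noise_vars) {
  if (length(gains) != length(noise_vars) || length(gains) < 1) {
    stop("gains and noise_vars must have equal positive length", call. = FALSE)
  }
  if (any(noise_vars <= 0)) stop("noise variances must be positive", call. = FALSE)
  n <- length(gains)
  10 * log10(a^2 / n * sum(gains^2 / noise_vars))
}
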