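#' Canonical electrophysiological frequency bands
#'
#' The six canonical bands used throughout the package, in fixed order:
#' delta (2--4 Hz), theta (5--7 Hz), alpha (8--12 Hz), beta (15--29 Hz),
#' low gamma (30--59 Hz), and high gamma (60--90 Hz).
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz), one row per band.
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "lgamma", "hgamma"),
    lo = c(2, 5, 8, 15, 30, 60),
    hi = c(4, 7, 12, 29, 59, 90),
    stringsAsFactors = FALSE
  )
}

#' Construct a frequency band
#'
#' @param name Band label.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return A `frequency_band` list with elements `name`, `lo`, `hi`.
#' @export
frequency_band <- function(name, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo) {
    stop("frequency band requires 0 < lo < hi", call. = FALSE)
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "frequency_band")
}

#' @keywords internal
#' @noRd
as_band <- function(x) {
  if (inherits(x, "frequency_band")) return(x)
  if (is.character(x) && length(x) == 1) {
    bands <- canonical_bands()
    i <- match(x, bands$name)
    if (is.na(i)) stop("unknown band name: ", x, call. = FALSE)
    return(frequency_band(bands$name[i], bands$lo[i], bands$hi[i]))
  }
  stop("cannot interpret band specification", call. = FALSE)
}
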