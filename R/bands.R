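#' Canonical olfactory-bulb LFP frequency bands
#'
#' Returns the four analysis bands used throughout the package: theta
#' (6--12 Hz), beta (15--30 Hz), low gamma (35--55 Hz) and high gamma
#' (65--95 Hz).
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  data.frame(
    band = c("theta", "beta", "low_gamma", "high_gamma"),
    f_lo = c(6, 15, 35, 65),
    f_hi = c(12, 30, 55, 95),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands, fs = NULL) {
  stopifnot(is.data.frame(bands), all(c("band", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo)) {
    stop("invalid band edges: need 0 < f_lo < f_hi", call. = FALSE)
  }
  if (!is.null(fs) && any(bands$f_hi >= fs / 2)) {
    stop("band edge at or above Nyquist (fs/2 = ", fs / 2, " Hz)", call. = FALSE)
  }
  invisible(bands)
}
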