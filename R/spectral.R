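#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the output has no group delay -- required so
#' that lick/phase relationships are undistorted downstream.
#'
#' @param x Numeric vector (one electrode trace).
#' @param f_lo,f_hi Band edges, Hz.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth order per pass (default 4; the effective
#'   magnitude response is squared by the two passes).
#' @return Filtered vector, same length.
#' @export
bandpass <- function(x, f_lo, f_hi, fs, order = 4L) {
  if (f_lo <= 0 || f_hi <= f_lo) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= fs / 2) stop("f_hi at or above Nyquist (fs/2)", call. = FALSE)
  bt <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  signal::filtfilt(bt, x)
}

#' Sliding-window spectrogram in decibels
#'
#' Short-time power spectral density over a sliding window (default 1 s,
#' giving 1 Hz frequency resolution), Hann-tapered, expressed as
#' 10*log10(PSD) with a configurable floor. The underlying STFT is
#' [signal::specgram()]; this function applies one-sided PSD scaling
#' (power in microvolt^2/Hz) so that summing the PSD over frequency times the
#' bin width recovers the signal variance (Parseval).
#'
#' Input sampled above 1000 Hz is decimated (anti-aliased) to 1000 Hz first:
#' all analysis bands lie at or below 95 Hz.
#'
#' @param x Numeric vector, microvolts.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 1).
#' @param step_s Step between window starts, seconds (default 0.1).
#' @param t0 Time of the first sample, seconds.
#' @param db_floor Floor in dB applied after conversion (default -120),
#'   keeping silent channels finite.
#' @param taper `"hann"` (default) or `"hamming"`.
#' @return Object of class `lfp_spectrogram`: list with `power_db`
#'   (`n_time x n_freq`), `time_s` (window centers), `freq_hz`, and the
#'   window parameters.
#' @export
lfp_spectrogram <- function(x, fs, window_s = 1, step_s = 0.1, t0 = 0,
                            db_floor = -120, taper = c("hann", "hamming")) {
  taper <- match.arg(taper)
  if (fs > 1000) {
    dec <- round(fs / 1000)
    x <- signal::decimate(x, dec, ftype = "fir")
    fs <- fs / dec
  }
  n_win <- round(window_s * fs)
  n_step <- max(1L, round(step_s * fs))
  if (length(x) < n_win) stop("signal shorter than the window", call. = FALSE)
  w <- if (taper == "hann") signal::hanning(n_win) else signal::hamming(n_win)
  sp <- signal::specgram(x, n = n_win, Fs = fs, window = w,
                         overlap = n_win - n_step)
  # one-sided PSD scaling with window power normalization
  psd <- (Mod(sp$S)^2) / (fs * sum(w^2))
  psd[-1, ] <- 2 * psd[-1, ]            # double all but DC
  power_db <- t(10 * log10(pmax(psd, 10^(db_floor / 10))))
  # specgram's t is the time of the first sample of each window (1-based/fs)
  centers <- t0 + sp$t - 1 / fs + (n_win - 1) / (2 * fs)
  structure(list(power_db = power_db, time_s = centers, freq_hz = sp$f,
                 window_s = window_s, step_s = n_step / fs,
                 db_floor = db_floor, taper = taper, fs = fs),
            class = "lfp_spectrogram")
}

# indices of time bins whose window CENTER lies in [start, end)
spec_time_bins <- function(spec, start_s, end_s) {
  which(spec$time_s >= start_s & spec$time_s < end_s)
}

spec_freq_bins <- function(spec, f_lo, f_hi) {
  which(spec$freq_hz >= f_lo & spec$freq_hz <= f_hi)
}

check_coverage <- function(spec, start_s, end_s, what) {
  if (!length(spec_time_bins(spec, start_s, end_s))) {
    stop("spectrogram does not cover the ", what, " interval [",
         round(start_s, 3), ", ", round(end_s, 3), ") s", call. = FALSE)
  }
}

#' Odorant-evoked change in band power (delta power)
#'
#' The central statistic: mean dB power over the 2 s of odorant application
#' minus mean dB power over the baseline interval 2.1 to 0.6 s before
#' odorant onset, within one frequency band. Averaging is done on the dB
#' scale. A time bin belongs to an interval iff its window center lies in the
#' half-open interval `[start, end)`.
#'
#' @param spec An [lfp_spectrogram()].
#' @param odorant_onset_s Odorant onset, seconds.
#' @param f_lo,f_hi Band edges, Hz.
#' @param odor_window_s Length of the odorant analysis window (default 2).
#' @param baseline_from_s,baseline_to_s Baseline window, seconds before
#'   onset (defaults 2.1 and 0.6).
#' @return Delta power, dB (scalar).
#' @export
delta_power <- function(spec, odorant_onset_s, f_lo, f_hi,
                        odor_window_s = 2, baseline_from_s = 2.1,
                        baseline_to_s = 0.6) {
  check_coverage(spec, odorant_onset_s - baseline_from_s,
                 odorant_onset_s - baseline_to_s, "baseline")
  check_coverage(spec, odorant_onset_s, odorant_onset_s + odor_window_s,
                 "odorant")
  fb <- spec_freq_bins(spec, f_lo, f_hi)
  if (!length(fb)) stop("no frequency bins in [", f_lo, ", ", f_hi, "] Hz",
                        call. = FALSE)
  odor <- spec_time_bins(spec, odorant_onset_s, odorant_onset_s + odor_window_s)
  base <- spec_time_bins(spec, odorant_onset_s - baseline_from_s,
                         odorant_onset_s - baseline_to_s)
  mean(spec$power_db[odor, fb]) - mean(spec$power_db[base, fb])
}

#' Per-frequency delta power spectrum
#'
#' As [delta_power()] but resolved per frequency bin over a range (default
#' 4--100 Hz, theta through high gamma).
#'
#' @inheritParams delta_power
#' @param f_range Frequency range, Hz.
#' @return Data.frame `freq_hz`, `delta_db`.
#' @export
delta_power_spectrum <- function(spec, odorant_onset_s, f_range = c(4, 100),
                                 odor_window_s = 2, baseline_from_s = 2.1,
                                 baseline_to_s = 0.6) {
  check_coverage(spec, odorant_onset_s - baseline_from_s,
                 odorant_onset_s - baseline_to_s, "baseline")
  check_coverage(spec, odorant_onset_s, odorant_onset_s + odor_window_s,
                 "odorant")
  fb <- spec_freq_bins(spec, f_range[1], f_range[2])
  odor <- spec_time_bins(spec, odorant_onset_s, odorant_onset_s + odor_window_s)
  base <- spec_time_bins(spec, odorant_onset_s - baseline_from_s,
                         odorant_onset_s - baseline_to_s)
  data.frame(
    freq_hz = spec$freq_hz[fb],
    delta_db = colMeans(spec$power_db[odor, fb, drop = FALSE]) -
      colMeans(spec$power_db[base, fb, drop = FALSE])
  )
}

#' Per-trial, per-electrode, per-band delta power table
#'
#' Computes the full-session spectrogram of every electrode once, then
#' evaluates [delta_power()] around each trial's odorant onset for each band.
#'
#' @param bundle A [session_bundle()].
#' @param bands Band table (default [default_bands()]).
#' @param trial_indices Subset of trials (default all).
#' @param window_s,step_s Spectrogram parameters.
#' @param ... Passed to [delta_power()].
#' @return Long data.frame: `trial_index`, `electrode`, `band`, `delta_db`,
#'   `odorant_valence`, `outcome`, `laser` (logical).
#' @export
delta_power_table <- function(bundle, bands = default_bands(),
                              trial_indices = NULL, window_s = 1,
                              step_s = 0.1, ...) {
  validate_bands(bands, bundle$lfp$sampling_rate_hz)
  trials <- bundle$trials
  if (!is.null(trial_indices)) {
    trials <- trials[trials$trial_index %in% trial_indices, , drop = FALSE]
  }
  n_el <- nrow(bundle$lfp$signal)
  out <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    spec <- lfp_spectrogram(bundle$lfp$signal[e, ], bundle$lfp$sampling_rate_hz,
                            window_s = window_s, step_s = step_s,
                            t0 = bundle$lfp$t0)
    rows <- lapply(seq_len(nrow(trials)), function(i) {
      dd <- vapply(seq_len(nrow(bands)), function(b) {
        delta_power(spec, trials$odorant_onset_s[i], bands$f_lo[b],
                    bands$f_hi[b], ...)
      }, numeric(1))
      data.frame(trial_index = trials$trial_index[i], electrode = e,
                 band = bands$band, delta_db = dd,
                 odorant_valence = trials$odorant_valence[i],
                 outcome = if ("outcome" %in% names(trials))
                   trials$outcome[i] else NA_character_,
                 laser = !is.na(trials$laser_on_s[i]),
                 stringsAsFactors = FALSE)
    })
    out[[e]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
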