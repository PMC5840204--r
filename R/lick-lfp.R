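# analytic signal via FFT: zero negative frequencies, double positives
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Detect lick onsets
#'
#' For a continuous contact signal: rising-edge threshold crossing at the
#' half-range level. For an event-time list: pass-through. Either way, onsets
#' closer than the debounce interval to the previous onset are merged
#' (contact bounce).
#'
#' @param x Either a numeric contact signal (then give `fs`) or a numeric
#'   vector of event times in seconds (then leave `fs = NULL`).
#' @param fs Sampling rate of the contact signal, Hz; `NULL` means `x` holds
#'   event times.
#' @param t0 Time of the first sample of the contact signal, seconds.
#' @param debounce_s Minimum separation between onsets (default 0.07 s).
#' @return Numeric vector of onset times, seconds.
#' @export
detect_lick_onsets <- function(x, fs = NULL, t0 = 0, debounce_s = 0.07) {
  if (is.null(fs)) {
    times <- sort(x)
  } else {
    thr <- (max(x) + min(x)) / 2
    above <- x > thr
    idx <- which(diff(above) == 1) + 1L
    times <- t0 + (idx - 1) / fs
  }
  if (!length(times)) return(numeric(0))
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= debounce_s) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

#' Lick-triggered LFP average with bootstrap confidence band
#'
#' Aligns the raw LFP on lick onsets over lags -0.5 to +0.5 s (the
#' lick-related LFP, LR-LFP), averages across licks, and attaches a
#' percentile bootstrap 95% band obtained by resampling licks.
#'
#' @param lfp_trace One electrode trace, microvolts.
#' @param fs Sampling rate, Hz.
#' @param onsets Lick onset times, seconds.
#' @param t0 Time of the first LFP sample, seconds.
#' @param lag_range Lag window around each lick, seconds.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `lick_erp`: `lag_s`, `mean_uv`, `ci_lo`, `ci_hi`,
#'   `n_licks` (used), `n_dropped` (licks whose window left the record).
#' @export
lick_triggered_average <- function(lfp_trace, fs, onsets, t0 = 0,
                                   lag_range = c(-0.5, 0.5), n_boot = 1000L,
                                   seed = 1L, conf = 0.95) {
  snip <- lick_snippets(lfp_trace, fs, onsets, t0, lag_range)
  if (nrow(snip$mat) < 5) {
    stop("need >= 5 usable licks (", nrow(snip$mat), " available)", call. = FALSE)
  }
  m <- colMeans(snip$mat)
  alpha <- (1 - conf) / 2
  ci <- withr::with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      colMeans(snip$mat[sample.int(nrow(snip$mat), replace = TRUE), ,
                        drop = FALSE])
    }, numeric(ncol(snip$mat)))
    apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  })
  structure(list(lag_s = snip$lag_s, mean_uv = m,
                 ci_lo = pmin(ci[1, ], m), ci_hi = pmax(ci[2, ], m),
                 n_licks = nrow(snip$mat), n_dropped = snip$n_dropped),
            class = "lick_erp")
}

lick_snippets <- function(lfp_trace, fs, onsets, t0, lag_range) {
  lag_idx <- round(lag_range[1] * fs):round(lag_range[2] * fs)
  centers <- round((onsets - t0) * fs) + 1L
  ok <- centers + lag_idx[1] >= 1 & centers + lag_idx[length(lag_idx)] <= length(lfp_trace)
  mat <- t(vapply(centers[ok], function(c0) lfp_trace[c0 + lag_idx],
                  numeric(length(lag_idx))))
  if (sum(ok) == 1) mat <- matrix(mat, nrow = 1)
  list(mat = mat, lag_s = lag_idx / fs, n_dropped = sum(!ok))
}

#' Theta phase of lick onsets
#'
#' Zero-phase filters the LFP to the theta band, takes the analytic signal
#' (Hilbert), and evaluates its phase at each lick onset. Phase convention:
#' 0 at the oscillation peak, increasing with time, wrapped to `[-pi, pi)`.
#'
#' @param lfp_trace One electrode trace.
#' @param fs Sampling rate, Hz.
#' @param onsets Lick onset times, seconds.
#' @param t0 Time of the first sample, seconds.
#' @param f_lo,f_hi Theta band edges (default 6--12 Hz).
#' @return Object of class `phase_result`: `phases` (per lick),
#'   `circular_mean`, `R` (resultant length), `n`.
#' @export
lick_theta_phase <- function(lfp_trace, fs, onsets, t0 = 0,
                             f_lo = 6, f_hi = 12) {
  if (length(onsets) < 5) stop("need >= 5 licks", call. = FALSE)
  theta <- bandpass(lfp_trace, f_lo, f_hi, fs)
  phase <- Arg(analytic_signal(theta))
  idx <- round((onsets - t0) * fs) + 1L
  idx <- idx[idx >= 1 & idx <= length(phase)]
  ph <- phase[idx]
  cs <- circular_stats(ph)
  structure(list(phases = ph, circular_mean = cs$mean, R = cs$R,
                 n = length(ph)), class = "phase_result")
}

# theta-peak surrogate alignment events within a window, optionally offset by
# phases resampled from observed lick phases (like-with-like baseline);
# phase_w is the precomputed wrapped theta phase of the trace
surrogate_events <- function(phase_w, fs, t0, window, phase_pool = NULL,
                             f_lo = 6, f_hi = 12) {
  # peaks: upward zero crossings of the wrapped phase (phase 0 = peak)
  cross <- which(diff(sign(phase_w)) > 0 & abs(diff(phase_w)) < pi) + 1L
  times <- t0 + (cross - 1) / fs
  times <- times[times >= window[1] & times <= window[2]]
  if (length(times) && !is.null(phase_pool) && length(phase_pool)) {
    f_c <- (f_lo + f_hi) / 2
    off <- sample(phase_pool, length(times), replace = TRUE)
    times <- times + off / (2 * pi * f_c)
  }
  sort(times)
}

#' Lick-related LFP delta power per trial
#'
#' For each trial: align the LFP on the trial's lick onsets within the 2 s
#' odorant window, average, and evaluate the sliding-window spectrogram of
#' that lick-locked trace in one band at a requested lag from lick onset.
#' The same quantity computed from baseline alignment events (theta peaks in
#' the pre-odorant baseline window, offset by phases resampled from the
#' trial's real licks) is subtracted, yielding a per-trial LR-LFP delta power
#' suited to the same ROC machinery as ordinary delta power. Trials without
#' licks in the odorant window (typically CR and Miss) use theta-peak
#' surrogate events on both sides, unless `surrogate = FALSE`, in which case
#' they are flagged excluded.
#'
#' @param bundle A [session_bundle()].
#' @param electrode Electrode index.
#' @param f_lo,f_hi Band edges, Hz.
#' @param lag_s Lag from lick onset at which band power is evaluated
#'   (default 0.3 s).
#' @param trial_indices Subset of trials (default all).
#' @param window_s Spectrogram window for the lick-locked trace (default
#'   0.5 s; the trace is only ~1 s long plus margins).
#' @param odor_window_s Window after odorant onset in which licks are used.
#' @param baseline_from_s,baseline_to_s Pre-odorant baseline window bounds,
#'   seconds before onset.
#' @param surrogate Use theta-peak surrogate alignment events for lickless
#'   trials (default `TRUE`).
#' @param seed Seed for the phase resampling of baseline events.
#' @return Data.frame `trial_index`, `delta_db`, `n_events`, `excluded`,
#'   `odorant_valence`, `outcome`.
#' @export
lr_lfp_delta_power <- function(bundle, electrode, f_lo, f_hi, lag_s = 0.3,
                               trial_indices = NULL, window_s = 0.5,
                               odor_window_s = 2, baseline_from_s = 2.1,
                               baseline_to_s = 0.6, surrogate = TRUE,
                               seed = 1L) {
  withr::with_seed(seed, {
    lr_lfp_delta_power_impl(bundle, electrode, f_lo, f_hi, lag_s,
                            trial_indices, window_s, odor_window_s,
                            baseline_from_s, baseline_to_s, surrogate)
  })
}

lr_lfp_delta_power_impl <- function(bundle, electrode, f_lo, f_hi, lag_s,
                                    trial_indices, window_s, odor_window_s,
                                    baseline_from_s, baseline_to_s, surrogate) {
  fs <- bundle$lfp$sampling_rate_hz
  t0 <- bundle$lfp$t0
  x <- bundle$lfp$signal[electrode, ]
  trials <- bundle$trials
  if (!is.null(trial_indices)) {
    trials <- trials[trials$trial_index %in% trial_indices, , drop = FALSE]
  }
  margin <- window_s / 2 + 0.05
  lag_range <- c(-0.5 - margin, 0.5 + margin)
  # theta phase of the whole trace, computed once and reused for surrogate
  # events and per-trial lick phases
  phase_w <- Arg(analytic_signal(bandpass(x, 6, 12, fs)))
  # session-wide lick statistics: surrogate events on lickless trials mimic
  # the observed lick process (its theta phase jitter and its count), so the
  # two trial classes are aligned on like-for-like events
  all_li <- round((bundle$licks$time_s - t0) * fs) + 1L
  session_pool <- phase_w[all_li[all_li >= 1 & all_li <= length(phase_w)]]
  per_trial_n <- table(bundle$licks$trial_index)
  typical_n <- if (length(per_trial_n)) round(stats::median(per_trial_n)) else 0L

  band_at_lag <- function(events) {
    snip <- lick_snippets(x, fs, events, t0, lag_range)
    if (!nrow(snip$mat)) return(NA_real_)
    erp <- colMeans(snip$mat)
    spec <- lfp_spectrogram(erp, fs, window_s = window_s, step_s = 0.05,
                            t0 = snip$lag_s[1])
    fb <- spec_freq_bins(spec, f_lo, f_hi)
    tb <- which.min(abs(spec$time_s - lag_s))
    if (abs(spec$time_s[tb] - lag_s) > spec$step_s) return(NA_real_)
    mean(spec$power_db[tb, fb])
  }

  rows <- lapply(seq_len(nrow(trials)), function(i) {
    on <- trials$odorant_onset_s[i]
    lt <- bundle$licks$time_s[bundle$licks$trial_index == trials$trial_index[i]]
    odor_licks <- lt[lt >= on & lt <= on + odor_window_s]
    ph <- NULL
    if (length(odor_licks)) {
      li <- round((odor_licks - t0) * fs) + 1L
      ph <- phase_w[li[li >= 1 & li <= length(phase_w)]]
    }
    if (!length(odor_licks)) {
      if (!surrogate) {
        return(data.frame(trial_index = trials$trial_index[i],
                          delta_db = NA_real_, n_events = 0L, excluded = TRUE,
                          odorant_valence = trials$odorant_valence[i],
                          outcome = trials$outcome[i], stringsAsFactors = FALSE))
      }
      odor_licks <- surrogate_events(phase_w, fs, t0, c(on, on + odor_window_s),
                                     phase_pool = session_pool)
      if (typical_n > 0 && length(odor_licks) > typical_n) {
        odor_licks <- sort(sample(odor_licks, typical_n))
      }
      ph <- if (length(session_pool)) session_pool else NULL
    }
    base_events <- surrogate_events(phase_w, fs, t0,
                                    c(on - baseline_from_s, on - baseline_to_s),
                                    phase_pool = ph)
    # match the baseline event count to the odor-window count so that the
    # averaging-noise term of the locked mean cancels in the subtraction
    if (length(base_events) > length(odor_licks)) {
      base_events <- sort(sample(base_events, length(odor_licks)))
    }
    odor_db <- band_at_lag(odor_licks)
    base_db <- band_at_lag(base_events)
    data.frame(trial_index = trials$trial_index[i],
               delta_db = odor_db - base_db,
               n_events = length(odor_licks),
               excluded = is.na(odor_db) || is.na(base_db),
               odorant_valence = trials$odorant_valence[i],
               outcome = trials$outcome[i], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Laser-induced change in auROC: opsin minus control (delta auROC)
#'
#' From a table of per-electrode auROC values in the four genotype x epoch
#' cells, computes per band (and optionally per lag)
#' `delta_auroc = (auROC_laser - auROC_pre)_opsin -
#' (auROC_laser - auROC_pre)_control`, a bootstrap confidence interval over
#' electrodes, the genotype-by-laser interaction p-value, and FDR correction
#' over the band (x lag) grid.
#'
#' @param auroc_table Data.frame with columns `genotype` (`"control"`,
#'   `"opsin"`), `epoch` (`"pre"`, `"laser"`), `electrode`, `band`,
#'   `auroc`, and optionally `lag_s`.
#' @param n_boot Bootstrap replicates for the CI (default 1000).
#' @param seed Integer seed.
#' @param q FDR target across the grid.
#' @param conf Confidence level.
#' @return Data.frame per band (x lag): `delta_auroc`, `ci_lo`, `ci_hi`,
#'   `interaction_p`, `significant` (FDR mask).
#' @export
delta_auroc_profile <- function(auroc_table, n_boot = 1000L, seed = 1L,
                                q = 0.05, conf = 0.95) {
  need <- c("genotype", "epoch", "electrode", "band", "auroc")
  miss <- setdiff(need, names(auroc_table))
  if (length(miss)) stop("auroc_table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("control", "opsin") %in% auroc_table$genotype) ||
      !all(c("pre", "laser") %in% auroc_table$epoch)) {
    stop("all four genotype x epoch cells must be present", call. = FALSE)
  }
  has_lag <- "lag_s" %in% names(auroc_table)
  keys <- unique(auroc_table[, c("band", if (has_lag) "lag_s"), drop = FALSE])
  alpha <- (1 - conf) / 2

  cell_change <- function(sub, geno, boot = FALSE) {
    pre <- sub$auroc[sub$genotype == geno & sub$epoch == "pre"]
    las <- sub$auroc[sub$genotype == geno & sub$epoch == "laser"]
    if (boot) {
      pre <- pre[sample.int(length(pre), replace = TRUE)]
      las <- las[sample.int(length(las), replace = TRUE)]
    }
    mean(las) - mean(pre)
  }

  rows <- withr::with_seed(seed, lapply(seq_len(nrow(keys)), function(i) {
    sel <- auroc_table$band == keys$band[i]
    if (has_lag) sel <- sel & auroc_table$lag_s == keys$lag_s[i]
    sub <- auroc_table[sel, , drop = FALSE]
    if (any(table(sub$genotype, sub$epoch) == 0)) {
      stop("missing genotype x epoch cell for band ", keys$band[i], call. = FALSE)
    }
    d_obs <- cell_change(sub, "opsin") - cell_change(sub, "control")
    boots <- vapply(seq_len(n_boot), function(b) {
      cell_change(sub, "opsin", boot = TRUE) -
        cell_change(sub, "control", boot = TRUE)
    }, numeric(1))
    ia <- interaction_anova(sub$auroc, sub$genotype, sub$epoch)
    cbind(keys[i, , drop = FALSE],
          data.frame(delta_auroc = d_obs,
                     ci_lo = unname(stats::quantile(boots, alpha)),
                     ci_hi = unname(stats::quantile(boots, 1 - alpha)),
                     interaction_p = ia$p_value, row.names = NULL))
  }))
  res <- do.call(rbind, rows)
  res$significant <- fdr_correct(res$interaction_p, q)$significant
  rownames(res) <- NULL
  res
}
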