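#' Configuration for the synthetic go/no-go session generator
#'
#' Every statistical assumption the analysis pipeline relies on is a
#' programmable parameter here: block-randomized trial order (10 S+ and 10 S-
#' per 20-trial block), odorant onset 1--1.5 s after port entry, 2.5 s odorant
#' delivery, a behavioral accuracy trajectory, per-band odorant-evoked power
#' changes in dB (optionally locked to odorant value or identity, ramped with
#' learning, and scaled by an optogenetic laser factor per genotype), 1/f
#' background noise, and licking phase-locked to a shared theta oscillator.
#'
#' @param seed Integer seed; identical seed and config give a byte-identical
#'   session.
#' @param n_trials Number of trials; a multiple of `block_size` is typical.
#' @param n_electrodes Number of electrodes.
#' @param sampling_rate_hz Simulation rate, Hz. 1000 Hz covers all analysis
#'   bands (<= 95 Hz) economically; raise it for higher-fidelity runs.
#' @param block_size Trials per randomization block, half S+ half S-.
#' @param p_correct Probability the simulated mouse responds correctly:
#'   a scalar, a vector of length `n_trials`, or a function of trial index.
#' @param band_effects Data.frame with columns `band`, `splus_db`,
#'   `sminus_db`: the programmed odorant-evoked change of band power (dB)
#'   for each valence class.
#' @param effect_scale Scalar or per-trial vector in `[0, 1]` multiplying the
#'   programmed dB changes -- a learning ramp when it rises across trials.
#' @param effect_sd_db Trial-to-trial SD (dB) of the realized evoked change,
#'   drawn independently per electrode (electrode-specific evoked
#'   variability, keeping electrodes exchangeable units).
#' @param effect_locked_to `"value"` (the effect follows the rewarded
#'   odorant), `"identity"` (the effect follows the chemical, the reversal
#'   control), or `"response"` (the effect follows the animal's go response,
#'   so false-alarm trials resemble hits).
#' @param background List with `exponent` (power ~ 1/f^exponent) and `rms_uv`.
#' @param osc_rms_uv Named numeric: baseline RMS amplitude (microvolts) of
#'   each band-limited oscillator.
#' @param lick_rate_hz Mean lick rate during response licking.
#' @param theta_freq_hz Centre frequency of the shared theta oscillator.
#' @param theta_lock_kappa Von Mises concentration of lick phases on theta.
#' @param theta_share Weight in `[0, 1]` of the shared theta oscillator in
#'   each electrode's theta component (the rest is electrode-specific
#'   narrowband noise).
#' @param laser_effect Named numeric `c(control = 1, opsin = ...)`:
#'   multiplicative factor applied to the S+/S- band contrast on laser
#'   trials. `control` must be 1.
#' @param mouse_id,genotype,odorant_pair,session_index,reward_mapping,laser_enabled
#'   Session metadata; see [session_meta()]. When `laser_enabled` is `TRUE`
#'   every trial gets a 3.5 s laser interval starting at port entry.
#' @return An object of class `sim_config` (named list).
#' @export
sim_config <- function(seed = 1L, n_trials = 100L, n_electrodes = 16L,
                       sampling_rate_hz = 1000,
                       block_size = 20L,
                       p_correct = 0.95,
                       band_effects = data.frame(
                         band = c("theta", "beta", "low_gamma", "high_gamma"),
                         splus_db = 6, sminus_db = 0),
                       effect_scale = 1,
                       effect_sd_db = 2,
                       effect_locked_to = c("value", "identity", "response"),
                       background = list(exponent = 1, rms_uv = 10),
                       osc_rms_uv = c(theta = 20, beta = 15,
                                      low_gamma = 10, high_gamma = 8),
                       lick_rate_hz = 7,
                       theta_freq_hz = 8,
                       theta_lock_kappa = 2,
                       theta_share = 0.7,
                       laser_effect = c(control = 1, opsin = 0),
                       mouse_id = "sim1", genotype = "control",
                       odorant_pair = "SIM", session_index = 1L,
                       reward_mapping = "A", laser_enabled = FALSE) {
  effect_locked_to <- match.arg(effect_locked_to)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$block_size %% 2 != 0) stop("block_size must be even", call. = FALSE)
  bands <- default_bands()
  bands <- bands[match(cfg$band_effects$band, bands$band), ]
  if (anyNA(bands$band)) stop("band_effects$band: unknown band name", call. = FALSE)
  validate_bands(bands, cfg$sampling_rate_hz)
  if (abs(cfg$laser_effect[["control"]] - 1) > 1e-12) {
    stop("laser_effect['control'] must be 1.0", call. = FALSE)
  }
  p <- resolve_p_correct(cfg$p_correct, cfg$n_trials)
  if (any(p < 0 | p > 1)) stop("p_correct outside [0, 1]", call. = FALSE)
  if (cfg$theta_share < 0 || cfg$theta_share > 1) {
    stop("theta_share outside [0, 1]", call. = FALSE)
  }
  if (cfg$lick_rate_hz <= 0) stop("lick_rate_hz must be > 0", call. = FALSE)
  invisible(cfg)
}

resolve_p_correct <- function(p, n_trials) {
  if (is.function(p)) p <- vapply(seq_len(n_trials), p, numeric(1))
  if (length(p) == 1) p <- rep(p, n_trials)
  if (length(p) != n_trials) stop("p_correct: wrong length", call. = FALSE)
  p
}

# --- random draws ----------------------------------------------------------

#' Draw from a von Mises distribution
#'
#' Best--Fisher rejection sampler. `kappa = 0` reduces to the circular
#' uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- wrap_pi(theta + mu)
      i <- i + 1L
    }
  }
  out
}

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Circular resultant length and mean
#'
#' @param phases Angles in radians.
#' @return List with `R` (resultant length in `[0, 1]`) and `mean`
#'   (circular mean, radians).
#' @export
circular_stats <- function(phases) {
  z <- mean(exp(1i * phases))
  list(R = Mod(z), mean = Arg(z))
}

# 1/f^a noise by spectral synthesis, unit RMS
one_over_f_noise <- function(n, fs, exponent = 1) {
  nf <- stats::nextn(n)
  w <- stats::rnorm(nf)
  W <- stats::fft(w)
  f <- c(0, seq_len(nf - 1)) * fs / nf
  f <- pmin(f, fs - f)              # two-sided frequency magnitude
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Gaussian noise confined to [f_lo, f_hi] by FFT masking, unit RMS
band_limited_noise <- function(n, fs, f_lo, f_hi, edge_hz = 1) {
  nf <- stats::nextn(n)
  w <- stats::rnorm(nf)
  W <- stats::fft(w)
  f <- c(0, seq_len(nf - 1)) * fs / nf
  f <- pmin(f, fs - f)
  mask <- numeric(nf)
  core <- f >= f_lo & f <= f_hi
  mask[core] <- 1
  lo_edge <- f > f_lo - edge_hz & f < f_lo
  mask[lo_edge] <- 0.5 * (1 + cos(pi * (f_lo - f[lo_edge]) / edge_hz))
  hi_edge <- f > f_hi & f < f_hi + edge_hz
  mask[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - f_hi) / edge_hz))
  x <- Re(stats::fft(W * mask, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Smoothly frequency-modulated phase process: f0 plus slow jitter
theta_phase_process <- function(n, fs, f0, jitter_sd = 0.4, jitter_dt = 0.5) {
  dur <- n / fs
  knots <- seq(0, dur + jitter_dt, by = jitter_dt)
  fk <- f0 + stats::rnorm(length(knots), 0, jitter_sd)
  f_inst <- stats::spline(knots, fk, xout = (seq_len(n) - 1) / fs)$y
  f_inst <- pmax(f_inst, f0 / 2)
  2 * pi * cumsum(f_inst) / fs
}

# phase at arbitrary times, interpolated between consecutive theta peaks
interp_phase <- function(times, peaks, cycle_rate) {
  if (length(peaks) < 2) return(2 * pi * cycle_rate * times)
  k <- findInterval(times, peaks)
  k0 <- pmax(pmin(k, length(peaks) - 1), 1)
  span <- peaks[k0 + 1] - peaks[k0]
  2 * pi * (times - peaks[k0]) / span
}

# times (relative to the phase vector origin) where phase crosses 2*pi*k,
# i.e. the peaks of cos(phase)
phase_peak_times <- function(phase, fs, t0 = 0) {
  k <- floor(phase / (2 * pi))
  idx <- which(diff(k) > 0)
  if (!length(idx)) return(numeric(0))
  # linear interpolation of the crossing within the sample step
  tgt <- 2 * pi * k[idx + 1]
  frac <- (tgt - phase[idx]) / (phase[idx + 1] - phase[idx])
  t0 + (idx - 1 + frac) / fs
}

# --- lick trains ------------------------------------------------------------

#' Simulate a theta-locked lick train
#'
#' Licks are generated one per theta cycle with thinning so that the expected
#' count is `rate_hz * (t_end - t_start)`; each retained lick is placed at a
#' phase offset drawn from a von Mises distribution with concentration
#' `kappa` around the theta peak (phase 0). A refractory interval merges
#' implausibly close licks.
#'
#' @param t_start,t_end Window, seconds.
#' @param rate_hz Mean lick rate (licks/s); must not exceed the theta rate.
#' @param theta_phase_fn Function time -> unwrapped theta phase (radians).
#'   `NULL` uses a constant-frequency oscillator at `theta_freq_hz`.
#' @param theta_freq_hz Frequency used when `theta_phase_fn` is `NULL`.
#' @param kappa Von Mises concentration of lick phases (0 = uniform).
#' @param refractory_s Minimum inter-lick interval (s).
#' @param seed Optional integer seed.
#' @return Data.frame with `time_s` and `phase` (the programmed offset from
#'   the theta peak, radians).
#' @export
simulate_lick_train <- function(t_start, t_end, rate_hz,
                                theta_phase_fn = NULL, theta_freq_hz = 8,
                                kappa = 0, refractory_s = 0.07, seed = NULL) {
  if (t_end <= t_start) stop("empty window", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  run <- function() {
    fs <- 1000
    tt <- seq(t_start, t_end, by = 1 / fs)
    phase <- if (is.null(theta_phase_fn)) 2 * pi * theta_freq_hz * tt
             else theta_phase_fn(tt)
    peaks <- phase_peak_times(phase, fs, t0 = t_start)
    lick_train_from_peaks(peaks, t_start, t_end, rate_hz, kappa, refractory_s)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

lick_train_from_peaks <- function(peaks, t_start, t_end, rate_hz, kappa,
                                  refractory_s = 0.07) {
  if (!length(peaks)) {
    return(data.frame(time_s = numeric(0), phase = numeric(0)))
  }
  cycle_rate <- length(peaks) / (t_end - t_start)
  if (kappa < 0.5) {
    # essentially unlocked licking: a refractory renewal process, whose rate
    # is exact and whose phases are uniform by construction
    if (rate_hz >= 1 / refractory_s) {
      stop("rate_hz incompatible with the refractory period", call. = FALSE)
    }
    mean_gap <- 1 / rate_hz - refractory_s
    times <- t_start + cumsum(refractory_s + stats::rexp(
      ceiling(2 * rate_hz * (t_end - t_start)) + 10, 1 / mean_gap))
    times <- times[times <= t_end]
    ph <- wrap_pi(interp_phase(times, peaks, cycle_rate))
    return(data.frame(time_s = times, phase = ph))
  }
  # refractory violations between adjacent kept cycles are dropped below;
  # estimate the loss probability and inflate the thinning rate so that the
  # realized rate stays near the requested one (phases remain von Mises)
  margin <- 2 * pi * (1 - refractory_s * cycle_rate)
  q <- if (margin <= 0) 0 else {
    d <- rvonmises(200, 0, kappa) - rvonmises(200, 0, kappa)
    mean(d < -margin)
  }
  p0 <- min(1, rate_hz / cycle_rate)
  p <- min(1, p0 / max(1 - p0 * q, 0.5))
  keep <- stats::runif(length(peaks)) < p
  peaks <- peaks[keep]
  if (!length(peaks)) {
    return(data.frame(time_s = numeric(0), phase = numeric(0)))
  }
  ph <- rvonmises(length(peaks), 0, kappa)
  times <- peaks + ph / (2 * pi * cycle_rate)
  o <- order(times)
  times <- times[o]; ph <- ph[o]
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) { keep[i] <- TRUE; last <- times[i] }
  }
  inside <- keep & times >= t_start & times <= t_end
  data.frame(time_s = times[inside], phase = ph[inside])
}

# --- session generator ------------------------------------------------------

#' Simulate a complete go/no-go session
#'
#' Generates block-randomized trials, a behavioral response per trial from the
#' accuracy trajectory, theta-locked lick trains on go responses (guaranteed
#' to satisfy the lick criterion, so the programmed response IS the outcome),
#' and continuous multi-electrode LFP: 1/f background plus four band-limited
#' oscillators whose amplitude steps by the realized dB change during odorant
#' delivery (100 ms cosine ramps). One shared frequency-modulated theta
#' oscillator drives both lick timing and (partially) every electrode's theta
#' component, producing lick--theta phase locking.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (a [session_bundle()]) and `truth` (ground
#'   truth: programmed per-trial dB changes per band (before the
#'   per-electrode variability draw), programmed responses and outcomes, and
#'   programmed lick phases).
#' @export
simulate_session <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_session_impl(config))
}

simulate_session_impl <- function(cfg) {
  fs <- cfg$sampling_rate_hz
  n_trials <- cfg$n_trials
  bands <- default_bands()
  eff <- cfg$band_effects[match(bands$band, cfg$band_effects$band), ]
  eff$splus_db[is.na(eff$band)] <- 0
  eff$sminus_db[is.na(eff$band)] <- 0

  lead_in <- 3; slot <- 6; odor_dur <- 2.5; resp_win <- 2
  dur <- lead_in + n_trials * slot + 2
  n <- round(dur * fs)

  # trial order: block-randomized, half S+ per block
  valence <- unlist(lapply(seq_len(ceiling(n_trials / cfg$block_size)), function(b) {
    sample(rep(c("Splus", "Sminus"), cfg$block_size / 2))
  }))[seq_len(n_trials)]
  odorant_id <- ifelse((valence == "Splus") == (cfg$reward_mapping == "A"), "A", "B")

  port_entry <- lead_in + (seq_len(n_trials) - 1) * slot
  onset <- port_entry + stats::runif(n_trials, 1.0, 1.5)

  # behavior: respond correctly with probability p
  p <- resolve_p_correct(cfg$p_correct, n_trials)
  correct <- stats::runif(n_trials) < p
  respond <- ifelse(valence == "Splus", correct, !correct)
  outcome <- ifelse(valence == "Splus", ifelse(respond, "Hit", "Miss"),
                    ifelse(respond, "FA", "CR"))

  # shared theta phase process
  phase <- theta_phase_process(n, fs, cfg$theta_freq_hz)
  all_peaks <- phase_peak_times(phase, fs, t0 = 0)

  # licks on respond trials, theta-locked, lick criterion guaranteed
  lick_list <- vector("list", n_trials)
  for (i in which(respond)) {
    w0 <- onset[i]; w1 <- onset[i] + resp_win
    pk <- all_peaks[all_peaks >= w0 & all_peaks <= w1]
    tr <- lick_train_from_peaks(pk, w0, w1, cfg$lick_rate_hz, cfg$theta_lock_kappa)
    # force >= 1 lick in each of the four 0.5 s criterion intervals
    for (k in 0:3) {
      a <- w0 + 0.5 * k; b <- a + 0.5
      if (!any(tr$time_s >= a & tr$time_s < b)) {
        cand <- pk[pk >= a & pk < b]
        add <- if (length(cand)) cand[1] else (a + b) / 2
        tr <- rbind(tr, data.frame(time_s = add, phase = 0))
      }
    }
    tr <- tr[order(tr$time_s), , drop = FALSE]
    tr <- tr[!duplicated(round(tr$time_s * fs)), , drop = FALSE]
    tr$trial_index <- i
    lick_list[[i]] <- tr
  }
  licks <- do.call(rbind, lick_list[!vapply(lick_list, is.null, logical(1))])
  if (is.null(licks)) {
    licks <- data.frame(time_s = numeric(0), phase = numeric(0),
                        trial_index = integer(0))
  }

  # programmed per-trial dB change per band (before electrode noise)
  scale <- cfg$effect_scale
  if (length(scale) == 1) scale <- rep(scale, n_trials)
  laser_fac <- if (cfg$laser_enabled) cfg$laser_effect[[cfg$genotype]] else 1
  delta_db <- matrix(0, n_trials, nrow(bands),
                     dimnames = list(NULL, bands$band))
  for (b in seq_len(nrow(bands))) {
    sp <- eff$splus_db[b]; sm <- eff$sminus_db[b]
    # the laser scales the S+/S- contrast (S- level kept fixed)
    sp_eff <- sm + laser_fac * (sp - sm)
    pos_class <- switch(cfg$effect_locked_to,
                        value = valence == "Splus",
                        identity = odorant_id == "A",
                        response = respond)
    delta_db[, b] <- ifelse(pos_class, sp_eff, sm) * scale
  }

  # LFP synthesis; the trial-to-trial evoked variability (effect_sd_db) is
  # drawn independently per electrode so that electrodes are exchangeable
  # observational units in the downstream statistics
  ramp_n <- round(0.1 * fs)
  ramp_shape <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
  make_env <- function(trial_db) {
    env <- rep(1, n)
    for (i in seq_len(n_trials)) {
      g <- 10^(trial_db[i] / 20)
      seg <- (round(onset[i] * fs)):(round((onset[i] + odor_dur) * fs))
      shape <- rep(1, length(seg))
      shape[seq_len(ramp_n)] <- ramp_shape
      shape[length(seg) + 1 - seq_len(ramp_n)] <- ramp_shape
      env[seg] <- 1 + (g - 1) * shape
    }
    env
  }

  shared_theta <- sqrt(2) * cos(phase)   # unit RMS
  w_sh <- cfg$theta_share
  rms <- cfg$osc_rms_uv[bands$band]

  sig <- matrix(0, cfg$n_electrodes, n)
  for (e in seq_len(cfg$n_electrodes)) {
    x <- cfg$background$rms_uv * one_over_f_noise(n, fs, cfg$background$exponent)
    for (b in seq_len(nrow(bands))) {
      gain <- exp(stats::rnorm(1, 0, 0.1))
      comp <- band_limited_noise(n, fs, bands$f_lo[b], bands$f_hi[b])
      if (bands$band[b] == "theta" && w_sh > 0) {
        comp <- w_sh * shared_theta + sqrt(1 - w_sh^2) * comp
      }
      env <- make_env(delta_db[, b] +
                        stats::rnorm(n_trials, 0, cfg$effect_sd_db))
      x <- x + rms[[b]] * gain * env * comp
    }
    sig[e, ] <- x
  }

  meta <- session_meta(cfg$mouse_id, cfg$genotype, cfg$odorant_pair,
                       cfg$session_index, fs, cfg$n_electrodes,
                       cfg$laser_enabled, cfg$reward_mapping)
  trials <- data.frame(
    trial_index = seq_len(n_trials),
    port_entry_s = port_entry,
    odorant_onset_s = onset,
    odorant_valence = valence,
    odorant_duration_s = odor_dur,
    laser_on_s = if (cfg$laser_enabled) port_entry else NA_real_,
    laser_off_s = if (cfg$laser_enabled) port_entry + 3.5 else NA_real_,
    outcome = outcome,
    stringsAsFactors = FALSE
  )
  lick_df <- licks[order(licks$trial_index, licks$time_s),
                   c("trial_index", "time_s")]
  rownames(lick_df) <- NULL
  bundle <- session_bundle(meta, lfp_record(sig, fs, 0), trials, lick_df)

  truth <- structure(list(
    trials = cbind(data.frame(trial_index = seq_len(n_trials),
                              odorant_valence = valence,
                              odorant_id = odorant_id,
                              p_correct = p, respond = respond,
                              outcome = outcome,
                              laser_factor = laser_fac,
                              stringsAsFactors = FALSE),
                   as.data.frame(delta_db)),
    licks = licks[order(licks$trial_index, licks$time_s),
                  c("trial_index", "time_s", "phase")],
    theta_freq_hz = cfg$theta_freq_hz,
    config = cfg
  ), class = "ground_truth")

  list(bundle = bundle, truth = truth)
}
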