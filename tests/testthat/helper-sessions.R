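# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small fast config: 250 Hz is enough for all bands (<= 95 Hz)
fast_config <- function(...) {
  args <- utils::modifyList(
    list(sampling_rate_hz = 250, n_trials = 40, n_electrodes = 2,
         effect_sd_db = 0),
    list(...))
  do.call(sim_config, args)
}

# a proficient session with a 6 dB beta contrast and no other effects
beta_session <- function() cached("beta_session", {
  simulate_session(fast_config(
    seed = 101,
    band_effects = data.frame(band = "beta", splus_db = 6, sminus_db = 0)))
})

# a null session: no programmed effect in any band
null_session <- function() cached("null_session", {
  simulate_session(fast_config(
    seed = 102, n_trials = 60, n_electrodes = 1,
    band_effects = data.frame(band = "beta", splus_db = 0, sminus_db = 0)))
})

# minimal hand-built one-trial bundle
tiny_bundle <- function(lick_times = c(11.1, 11.6, 12.2, 12.8)) {
  fs <- 250
  meta <- session_meta("m0", "control", "APEB", 1L, fs, 1L)
  lfp <- lfp_record(matrix(sin(2 * pi * 9 * (0:(20 * fs - 1)) / fs), 1), fs)
  trials <- data.frame(trial_index = 1L, port_entry_s = 9.8,
                       odorant_onset_s = 11.0, odorant_valence = "Splus",
                       odorant_duration_s = 2.5)
  licks <- data.frame(trial_index = rep(1L, length(lick_times)),
                      time_s = lick_times)
  if (!length(lick_times)) licks <- licks[0, ]
  session_bundle(meta, lfp, trials, licks)
}

# cosine-ramped repeated amplitude steps (gain over [onset, onset+step_len])
# applied to a base trace; returns the trace and the step onsets, so that
# delta-power estimates can be averaged over many independent realizations
stepped_trace <- function(base, fs, n_steps = 30, slot = 7.5, lead = 4,
                          step_len = 2.5, gain = 2, ramp_s = 0.1) {
  onsets <- lead + (seq_len(n_steps) - 1) * slot
  env <- rep(1, length(base))
  rn <- round(ramp_s * fs)
  for (on in onsets) {
    seg <- (round(on * fs)):(round((on + step_len) * fs))
    shape <- rep(1, length(seg))
    shape[seq_len(rn)] <- 0.5 * (1 - cos(pi * seq_len(rn) / rn))
    shape[length(seg) + 1 - seq_len(rn)] <- shape[seq_len(rn)]
    env[seg] <- 1 + (gain - 1) * shape
  }
  list(x = base * env, onsets = onsets)
}

stepped_trace_len <- function(fs, n_steps = 30, slot = 7.5, lead = 4) {
  round((lead + n_steps * slot + 2) * fs)
}
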