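test_that("the theta filter passes theta and rejects one octave out", {
  fs <- 1000
  t <- (0:19999) / fs
  y9 <- bandpass(sin(2 * pi * 9 * t), 6, 12, fs)
  expect_equal(max(abs(y9[5000:15000])), 1, tolerance = 0.05)
  y40 <- bandpass(sin(2 * pi * 40 * t), 6, 12, fs)
  # >= 40 dB attenuation well inside the stopband
  expect_lt(max(abs(y40[5000:15000])), 10^(-40 / 20))
  expect_error(bandpass(y9, 400, 600, fs), "Nyquist")
})

test_that("filtering is zero-phase: the impulse response is symmetric", {
  fs <- 250
  x <- numeric(5000); x[2500] <- 1
  h <- bandpass(x, 15, 30, fs)
  expect_equal(h[2500 + 1:200], h[2500 - 1:200], tolerance = 1e-6)
})

test_that("spectrogram power satisfies Parseval and localizes a sinusoid", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 40 * t)
  sp <- lfp_spectrogram(x, fs)
  peak <- sp$freq_hz[which.max(colMeans(sp$power_db))]
  expect_equal(peak, 40)
  # total power from the PSD equals the variance (one-sided scaling)
  psd_lin <- 10^(sp$power_db / 10)
  df <- sp$freq_hz[2] - sp$freq_hz[1]
  expect_equal(mean(rowSums(psd_lin)) * df, var(x), tolerance = 0.01)
})

test_that("spectrogram floors silent input and tracks variance in dB", {
  fs <- 250
  sp0 <- lfp_spectrogram(numeric(10 * fs), fs, db_floor = -120)
  expect_true(all(sp0$power_db == -120))

  withr::with_seed(4, {
    w <- rnorm(60 * fs)
    s1 <- lfp_spectrogram(w, fs)
    s2 <- lfp_spectrogram(sqrt(2) * w, fs)
    # doubling the variance raises every bin by 10*log10(2) = 3.01 dB
    expect_equal(mean(s2$power_db - s1$power_db), 10 * log10(2),
                 tolerance = 1e-6)
  })
})

test_that("delta power recovers an amplitude-doubling step and nulls out stationarity", {
  fs <- 250
  withr::with_seed(11, {
    n <- stepped_trace_len(fs)
    st <- stepped_trace(odorlfp:::band_limited_noise(n, fs, 15, 30), fs,
                        n_steps = 30, gain = 2)
  })
  sp <- lfp_spectrogram(st$x, fs)
  dd <- vapply(st$onsets, function(on) delta_power(sp, on, 15, 30), numeric(1))
  # amplitude x2 = +6.02 dB, averaged over 30 independent step realizations
  expect_equal(mean(dd), 20 * log10(2), tolerance = 0.5 / 6)
  # the same trace is stationary 5 s after each step: null
  d0 <- vapply(st$onsets + 5.0, function(on) delta_power(sp, on, 15, 30),
               numeric(1))
  expect_lt(abs(mean(d0)), 0.3)
  expect_error(delta_power(sp, 1, 15, 30), "baseline")
})

test_that("delta power is gain-invariant and consistent with its spectrum", {
  fs <- 250
  withr::with_seed(12, {
    n <- stepped_trace_len(fs, n_steps = 2)
    st <- stepped_trace(odorlfp:::band_limited_noise(n, fs, 15, 30), fs,
                        n_steps = 2)
  })
  sp1 <- lfp_spectrogram(st$x, fs)
  sp2 <- lfp_spectrogram(10 * st$x, fs)
  d1 <- delta_power(sp1, st$onsets[1], 15, 30)
  expect_equal(d1, delta_power(sp2, st$onsets[1], 15, 30), tolerance = 1e-9)
  # band delta equals the mean of the per-frequency delta over its bins
  dps <- delta_power_spectrum(sp1, st$onsets[1], f_range = c(15, 30))
  expect_equal(mean(dps$delta_db), d1, tolerance = 1e-9)
})

test_that("the delta power spectrum localizes a band-confined step", {
  fs <- 250
  n <- stepped_trace_len(fs, n_steps = 25)
  withr::with_seed(13, {
    # beta-only ramped step on an independent broadband floor
    st <- stepped_trace(odorlfp:::band_limited_noise(n, fs, 15, 30), fs,
                        n_steps = 25, gain = 2)
    x <- st$x + 0.3 * rnorm(n)
  })
  sp <- lfp_spectrogram(x, fs)
  dps_all <- lapply(st$onsets, function(on)
    delta_power_spectrum(sp, on, f_range = c(4, 100))$delta_db)
  dps <- Reduce(`+`, dps_all) / length(dps_all)
  freq <- delta_power_spectrum(sp, st$onsets[1], f_range = c(4, 100))$freq_hz
  expect_gt(mean(dps[freq >= 16 & freq <= 29]), 4)
  # elevation is confined: out-of-band bins average to ~0
  expect_lt(abs(mean(dps[freq >= 45])), 0.5)
  expect_lt(abs(mean(dps[freq <= 10])), 0.5)
})

test_that("a broadband step gives a flat delta power spectrum at the programmed dB", {
  fs <- 250
  n <- stepped_trace_len(fs, n_steps = 25)
  withr::with_seed(14, {
    st <- stepped_trace(rnorm(n), fs, n_steps = 25, gain = sqrt(2))
  })
  sp <- lfp_spectrogram(st$x, fs)
  dps_all <- lapply(st$onsets, function(on)
    delta_power_spectrum(sp, on)$delta_db)
  dps <- Reduce(`+`, dps_all) / length(dps_all)
  # variance x2 everywhere = 3.01 dB, flat across frequency bands
  expect_equal(mean(dps), 10 * log10(2), tolerance = 0.3 / 3)
  freq <- delta_power_spectrum(sp, st$onsets[1])$freq_hz
  expect_lt(abs(mean(dps[freq <= 30]) - mean(dps[freq >= 60])), 1)
})

test_that("input above 1 kHz is decimated without changing band power", {
  fs <- 2000
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  sp <- lfp_spectrogram(x, fs)
  expect_equal(sp$fs, 1000)
  peak <- sp$freq_hz[which.max(colMeans(sp$power_db))]
  expect_equal(peak, 20)
})

test_that("delta_power_table carries trial labels and one row per combination", {
  sim <- beta_session()
  dpt <- cached("beta_dpt", delta_power_table(sim$bundle))
  expect_equal(nrow(dpt), 40 * 2 * 4)
  expect_setequal(unique(dpt$band), default_bands()$band)
  expect_identical(
    dpt$odorant_valence[match(1:40, dpt$trial_index)],
    sim$bundle$trials$odorant_valence)
})
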