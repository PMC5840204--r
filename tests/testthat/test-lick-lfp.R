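test_that("lick onset detection thresholds, debounces and passes through", {
  fs <- 1000
  x <- numeric(5 * fs)
  true_on <- c(1.0, 2.0, 3.5)
  for (o in true_on) x[(o * fs + 1):(o * fs + 50)] <- 1
  expect_equal(detect_lick_onsets(x, fs), true_on, tolerance = 1e-9)

  # double bounce 20 ms after the contact break is merged
  x3 <- x; x3[(2.06 * fs + 1):(2.06 * fs + 10)] <- 1
  expect_equal(detect_lick_onsets(x3, fs), c(1.0, 2.0, 3.5), tolerance = 1e-9)

  # event-list input: pass-through with debounce merging
  expect_equal(detect_lick_onsets(c(1, 1.02, 1.5)), c(1, 1.5))
  expect_equal(detect_lick_onsets(numeric(0)), numeric(0))
})

test_that("ground-truth lick times survive the round trip through events", {
  sim <- beta_session()
  got <- detect_lick_onsets(sim$bundle$licks$time_s, debounce_s = 0.0)
  expect_equal(got, sort(sim$truth$licks$time_s))
})

test_that("the lick-triggered average recovers a deterministic waveform", {
  fs <- 250
  x <- numeric(60 * fs)
  onsets <- seq(2, 58, by = 1.5)
  wav <- sin(2 * pi * 10 * seq(0, 0.2, by = 1 / fs)) * 30
  for (o in onsets) {
    i0 <- round(o * fs) + 1
    x[i0:(i0 + length(wav) - 1)] <- x[i0:(i0 + length(wav) - 1)] + wav
  }
  erp <- lick_triggered_average(x, fs, onsets, n_boot = 100, seed = 1)
  at0 <- which(erp$lag_s == 0)
  expect_equal(erp$mean_uv[at0 + seq_along(wav) - 1], wav, tolerance = 1e-9)
  expect_true(all(erp$ci_lo <= erp$mean_uv & erp$mean_uv <= erp$ci_hi))
  expect_equal(erp$n_licks, length(onsets))
  # linearity
  erp2 <- lick_triggered_average(2 * x, fs, onsets, n_boot = 50, seed = 1)
  expect_equal(erp2$mean_uv, 2 * erp$mean_uv, tolerance = 1e-12)
})

test_that("licks uncorrelated with noise give a flat average within its CI", {
  fs <- 250
  withr::with_seed(55, {
    x <- rnorm(120 * fs, sd = 20)
    onsets <- sort(runif(150, 1, 119))
  })
  erp <- lick_triggered_average(x, fs, onsets, n_boot = 300, seed = 2)
  covered <- mean(erp$ci_lo <= 0 & 0 <= erp$ci_hi)
  expect_gte(covered, 0.85)
  expect_error(lick_triggered_average(x, fs, c(1, 2), n_boot = 10),
               ">= 5")
})

test_that("lick theta phase uses the peak-zero convention and detects locking", {
  fs <- 1000
  t <- (0:(80 * fs - 1)) / fs
  x <- cos(2 * pi * 9 * t)
  peaks <- (10:600) / 9
  pr <- lick_theta_phase(x, fs, peaks)
  expect_lt(abs(pr$circular_mean), 0.1)
  expect_gt(pr$R, 0.97)

  withr::with_seed(56, uni <- sort(runif(1000, 1, 79)))
  expect_lt(lick_theta_phase(x, fs, uni)$R, 0.1)
})

test_that("phase estimates are invariant to shifting LFP and licks together", {
  fs <- 250
  sim <- null_session()
  x <- sim$bundle$lfp$signal[1, ]
  dur <- length(x) / fs
  onsets <- sim$bundle$licks$time_s
  onsets <- onsets[onsets > 10 & onsets < dur - 10]
  p1 <- lick_theta_phase(x, fs, onsets)
  # prepend 8 s of signal: every lick sees the same samples, 8 s later
  shift <- 8
  x2 <- c(x[1:(shift * fs)], x)
  p2 <- lick_theta_phase(x2, fs, onsets + shift)
  expect_equal(p2$phases, p1$phases, tolerance = 1e-3)
  expect_equal(p2$R, p1$R, tolerance = 1e-4)
})

test_that("LR-LFP delta power recovers a lick-locked theta effect and nulls out", {
  # S+ trials double their theta amplitude: theta LR-LFP delta separates classes
  sim <- cached("lr_theta_session", simulate_session(fast_config(
    seed = 107, n_trials = 40, n_electrodes = 1,
    band_effects = data.frame(band = "theta", splus_db = 6, sminus_db = 0))))
  lr <- lr_lfp_delta_power(sim$bundle, 1, 6, 12, lag_s = 0.3)
  ok <- !lr$excluded
  r <- auroc_centered(lr$delta_db[ok & lr$outcome == "Hit"],
                      lr$delta_db[ok & lr$outcome == "CR"], "hit_cr")
  expect_gt(r$auroc, 0.3)

  # no programmed effect: auROC near zero averaged over seeds
  null_aurocs <- vapply(1:4, function(s) {
    s0 <- simulate_session(fast_config(
      seed = 110 + s, n_trials = 40, n_electrodes = 1,
      band_effects = data.frame(band = "beta", splus_db = 0,
                                sminus_db = 0)))$bundle
    lr0 <- lr_lfp_delta_power(s0, 1, 6, 12, lag_s = 0.3)
    ok0 <- !lr0$excluded
    auroc_centered(lr0$delta_db[ok0 & lr0$outcome == "Hit"],
                   lr0$delta_db[ok0 & lr0$outcome == "CR"], "hit_cr")$auroc
  }, numeric(1))
  expect_lt(abs(mean(null_aurocs)), 0.12)

  # the lag parameter is honored
  lr_lag0 <- lr_lfp_delta_power(sim$bundle, 1, 6, 12, lag_s = 0)
  expect_false(isTRUE(all.equal(lr$delta_db, lr_lag0$delta_db)))
})

test_that("delta auROC profile is null for identical genotypes and antisymmetric", {
  withr::with_seed(57, {
    base <- expand.grid(epoch = c("pre", "laser"), electrode = 1:8,
                        band = c("theta", "beta"), stringsAsFactors = FALSE)
    base$auroc <- rnorm(nrow(base), 0.2, 0.05)
    tab <- rbind(cbind(genotype = "control", base),
                 cbind(genotype = "opsin", base))  # identical groups
    prof <- delta_auroc_profile(tab, n_boot = 200, seed = 1)
    expect_true(all(prof$delta_auroc == 0))
    expect_false(any(prof$significant))

    # swapping genotype labels negates the profile exactly
    tab2 <- rbind(cbind(genotype = "control", base),
                  cbind(genotype = "opsin", base))
    tab2$auroc <- tab2$auroc + (tab2$genotype == "opsin" &
                                  tab2$epoch == "laser") * -0.3
    prof2 <- delta_auroc_profile(tab2, n_boot = 50, seed = 2)
    tab3 <- tab2
    tab3$genotype <- ifelse(tab3$genotype == "opsin", "control", "opsin")
    prof3 <- delta_auroc_profile(tab3, n_boot = 50, seed = 2)
    expect_equal(prof3$delta_auroc, -prof2$delta_auroc, tolerance = 1e-12)
    expect_error(delta_auroc_profile(tab2[tab2$genotype == "control", ]),
                 "cell")
  })
})
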