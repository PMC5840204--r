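#' Analysis configuration for the figure-level pipelines
#'
#' @param naive_n,proficient_n Trials per learning epoch (default 30, the
#'   first/last-30-trials convention).
#' @param laser_n Trials per pre-laser/laser epoch (default 20).
#' @param bands Band table (default [default_bands()]).
#' @param q Target false discovery rate.
#' @param n_perm Permutations for permutation tests.
#' @param seed Top-level seed; fanned out to all stochastic stages.
#' @param window_s,step_s Spectrogram parameters.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(naive_n = 30L, proficient_n = 30L, laser_n = 20L,
                            bands = default_bands(), q = 0.05,
                            n_perm = 1000L, seed = 1L,
                            window_s = 1, step_s = 0.1) {
  stopifnot(naive_n > 0, proficient_n > 0, laser_n > 0, n_perm > 0)
  validate_bands(bands)
  structure(list(naive_n = naive_n, proficient_n = proficient_n,
                 laser_n = laser_n, bands = bands, q = q, n_perm = n_perm,
                 seed = seed, window_s = window_s, step_s = step_s),
            class = "analysis_config")
}

epoch_delta_table <- function(sessions, epoch, config) {
  s <- sessions[[epoch$session]]
  delta_power_table(s, config$bands, trial_indices = epoch$trial_indices,
                    window_s = config$window_s, step_s = config$step_s)
}

#' Learning analysis: naive vs proficient value classification
#'
#' For each band, computes per-electrode S+/S- auROC of delta power in the
#' naive epoch (first trials of the first session) and the proficient epoch
#' (last trials of the last session), tests the difference with a permutation
#' ANOVA, and compares the percent of significantly classifying electrodes
#' between epochs with a chi-squared test.
#'
#' @param sessions List of [session_bundle()] objects in training order.
#' @param config An [analysis_config()].
#' @return Object of class `learning_report`: `roc` (per epoch x electrode x
#'   band auROC table), `by_band` (auROC means, permutation p, percent
#'   significant and chi-squared p per band), `config` echo.
#' @export
run_learning_analysis <- function(sessions, config = analysis_config()) {
  ep_naive <- select_epoch(sessions, "naive", config$naive_n)
  ep_prof <- select_epoch(sessions, "proficient", config$proficient_n)
  roc <- rbind(
    cbind(epoch = "naive",
          roc_by_electrode(epoch_delta_table(sessions, ep_naive, config),
                           "splus_sminus")),
    cbind(epoch = "proficient",
          roc_by_electrode(epoch_delta_table(sessions, ep_prof, config),
                           "splus_sminus")))
  ps <- percent_significant(roc, by = c("epoch", "band"), q = config$q)
  by_band <- do.call(rbind, lapply(unique(roc$band), function(b) {
    a_n <- roc$auroc[roc$epoch == "naive" & roc$band == b]
    a_p <- roc$auroc[roc$epoch == "proficient" & roc$band == b]
    if (length(a_n) < 2 || length(a_p) < 2) {
      warning("band ", b, ": n = 1 electrode family; permutation test ",
              "has no power", call. = FALSE)
    }
    pa <- permutation_anova(list(a_n, a_p), n_perm = config$n_perm,
                            seed = config$seed)
    kn <- ps[ps$epoch == "naive" & ps$band == b, ]
    kp <- ps[ps$epoch == "proficient" & ps$band == b, ]
    chi <- chi2_proportions(kn$k, kn$n, kp$k, kp$n)
    data.frame(band = b, auroc_naive = mean(a_n), auroc_proficient = mean(a_p),
               perm_anova_p = pa$p_value,
               pct_sig_naive = kn$percent, pct_sig_proficient = kp$percent,
               chi2_p = chi$p_value, stringsAsFactors = FALSE)
  }))
  structure(list(roc = roc, percent_significant = ps, by_band = by_band,
                 epochs = list(naive = ep_naive, proficient = ep_prof),
                 config = config),
            class = "learning_report")
}

#' Hit/CR/FA analysis of normalized delta power
#'
#' In the proficient epoch, normalizes per-electrode delta power to d'
#' (dividing by the mean class SD) and computes Hit/CR and FA/CR auROC per
#' electrode and band. Requires at least `min_fa` false-alarm trials; below
#' that the FA contrast is skipped with a report note.
#'
#' @param sessions List of [session_bundle()] in training order.
#' @param config An [analysis_config()].
#' @param min_fa Minimum FA trials (default 3).
#' @return Object of class `facr_report`: `roc` (contrast x electrode x band),
#'   `dprime` (per band: class means of d'), `notes`.
#' @export
run_facr_analysis <- function(sessions, config = analysis_config(),
                              min_fa = 3L) {
  ep <- select_epoch(sessions, "proficient", config$proficient_n)
  dpt <- epoch_delta_table(sessions, ep, config)
  n_fa <- length(unique(dpt$trial_index[dpt$outcome == "FA"]))
  notes <- character(0)
  roc <- cbind(contrast = "hit_cr", roc_by_electrode(dpt, "hit_cr"))
  if (n_fa >= min_fa) {
    roc <- rbind(roc, cbind(contrast = "fa_cr", roc_by_electrode(dpt, "fa_cr")))
  } else {
    notes <- c(notes, sprintf("only %d FA trials (< %d); FA/CR skipped",
                              n_fa, min_fa))
  }
  dprime <- do.call(rbind, lapply(unique(dpt$band), function(b) {
    sub <- dpt[dpt$band == b & dpt$outcome %in% c("Hit", "CR", "FA"), ]
    cls <- split(sub$delta_db, sub$outcome)
    cls <- cls[lengths(cls) >= 2]
    if (length(cls) < 2) return(NULL)
    dp <- dprime_normalize(cls)
    data.frame(band = b, class = names(dp$values),
               mean_dprime = vapply(dp$values, mean, numeric(1)),
               n = lengths(dp$values), divisor_db = dp$divisor,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(roc = roc, dprime = dprime, n_fa = n_fa, notes = notes,
                 epoch = ep, config = config),
            class = "facr_report")
}

#' Reward-reversal analysis: does delta power follow value or identity?
#'
#' Compares the per-odorant delta power between a forward session and a
#' reversed session (same odorant pair, opposite reward mapping), each over
#' its proficient (last `proficient_n` trials) epoch. If the evoked power
#' change follows odorant VALUE, the sign of
#' (delta power | odorant A) - (delta power | odorant B) flips between
#' sessions; if it follows identity it does not.
#'
#' @param forward_session,reversed_session [session_bundle()]s with opposite
#'   `reward_mapping`.
#' @param config An [analysis_config()].
#' @return Object of class `reversal_report`: per band the A-B difference in
#'   each session, permutation p-values for the forward/reversed difference
#'   per odorant, and `flip` (logical).
#' @export
run_reversal_analysis <- function(forward_session, reversed_session,
                                  config = analysis_config()) {
  if (forward_session$meta$reward_mapping ==
      reversed_session$meta$reward_mapping) {
    stop("sessions have the same reward_mapping; not a reversal", call. = FALSE)
  }
  tab <- function(s) {
    ep <- select_epoch(list(s), "proficient", config$proficient_n)
    d <- delta_power_table(s, config$bands, trial_indices = ep$trial_indices,
                           window_s = config$window_s, step_s = config$step_s)
    # odorant identity from valence + reward mapping
    d$odorant_id <- ifelse((d$odorant_valence == "Splus") ==
                             (s$meta$reward_mapping == "A"), "A", "B")
    d
  }
  fwd <- tab(forward_session); rev <- tab(reversed_session)
  by_band <- do.call(rbind, lapply(unique(fwd$band), function(b) {
    f <- fwd[fwd$band == b, ]; r <- rev[rev$band == b, ]
    dA_f <- mean(f$delta_db[f$odorant_id == "A"]) -
      mean(f$delta_db[f$odorant_id == "B"])
    dA_r <- mean(r$delta_db[r$odorant_id == "A"]) -
      mean(r$delta_db[r$odorant_id == "B"])
    pA <- permutation_anova(list(f$delta_db[f$odorant_id == "A"],
                                 r$delta_db[r$odorant_id == "A"]),
                            n_perm = config$n_perm, seed = config$seed)
    pB <- permutation_anova(list(f$delta_db[f$odorant_id == "B"],
                                 r$delta_db[r$odorant_id == "B"]),
                            n_perm = config$n_perm, seed = config$seed + 1L)
    data.frame(band = b, diff_forward = dA_f, diff_reversed = dA_r,
               perm_p_odorA = pA$p_value, perm_p_odorB = pB$p_value,
               flip = sign(dA_f) != sign(dA_r) &
                 pA$p_value < config$q & pB$p_value < config$q,
               stringsAsFactors = FALSE)
  }))
  structure(list(by_band = by_band, config = config),
            class = "reversal_report")
}

#' Optogenetic analysis: genotype-by-laser interaction
#'
#' Sessions are grouped by genotype from their metadata; the pre-laser epoch
#' is the last `laser_n` trials of the last no-laser session and the laser
#' epoch the first `laser_n` trials of the first laser session (per mouse).
#' Per band: per-electrode S+/S- (and Hit/CR) delta power auROC in the four
#' genotype x epoch cells, the interaction ANOVA, FDR over bands, and the
#' delta-auROC contrast with bootstrap CI. Behavior: percent correct pre vs
#' laser per mouse with a paired t-test.
#'
#' @param sessions List of [session_bundle()]s covering both genotypes, with
#'   laser and no-laser sessions per mouse.
#' @param config An [analysis_config()].
#' @param contrasts ROC contrasts to run (default S+/S- and Hit/CR).
#' @return Object of class `opto_report`: `roc` (cell table), `profile`
#'   (delta auROC per band via [delta_auroc_profile()]), `interaction`
#'   (per band x contrast), `behavior` (per-mouse percent correct pre/laser
#'   + paired t).
#' @export
run_opto_analysis <- function(sessions, config = analysis_config(),
                              contrasts = c("splus_sminus", "hit_cr")) {
  genotype <- vapply(sessions, function(s) s$meta$genotype, character(1))
  mouse <- vapply(sessions, function(s) s$meta$mouse_id, character(1))
  if (length(unique(genotype)) < 2) {
    stop("need sessions from both genotypes", call. = FALSE)
  }
  cells <- list()
  for (g in c("control", "opsin")) {
    for (mo in unique(mouse[genotype == g])) {
      ss <- sessions[genotype == g & mouse == mo]
      for (ep_label in c("pre_laser", "laser")) {
        ep <- select_epoch(ss, ep_label, config$laser_n)
        dpt <- delta_power_table(ss[[ep$session]], config$bands,
                                 trial_indices = ep$trial_indices,
                                 window_s = config$window_s,
                                 step_s = config$step_s)
        for (ctr in contrasts) {
          r <- roc_by_electrode(dpt, ctr)
          r$electrode <- paste(mo, r$electrode, sep = ":")
          cells[[length(cells) + 1L]] <- cbind(
            genotype = g, mouse = mo,
            epoch = if (ep_label == "pre_laser") "pre" else "laser",
            contrast = ctr, r)
        }
      }
    }
  }
  roc <- do.call(rbind, cells)
  interaction <- do.call(rbind, lapply(contrasts, function(ctr) {
    sub0 <- roc[roc$contrast == ctr, ]
    out <- do.call(rbind, lapply(unique(sub0$band), function(b) {
      sub <- sub0[sub0$band == b, ]
      ia <- interaction_anova(sub$auroc, sub$genotype, sub$epoch)
      data.frame(contrast = ctr, band = b, f = ia$statistic,
                 interaction_p = ia$p_value, stringsAsFactors = FALSE)
    }))
    out$significant <- fdr_correct(out$interaction_p, config$q)$significant
    out
  }))
  prof_in <- roc[roc$contrast == contrasts[1],
                 c("genotype", "epoch", "electrode", "band", "auroc")]
  profile <- delta_auroc_profile(prof_in, seed = config$seed, q = config$q)

  behavior <- do.call(rbind, lapply(unique(mouse), function(mo) {
    ss <- sessions[mouse == mo]
    pc <- vapply(c("pre_laser", "laser"), function(ep_label) {
      ep <- select_epoch(ss, ep_label, config$laser_n)
      ot <- classify_trials(ss[[ep$session]])
      100 * mean(ot$correct[ot$trial_index %in% ep$trial_indices])
    }, numeric(1))
    data.frame(mouse = mo, genotype = genotype[mouse == mo][1],
               pct_correct_pre = pc[[1]], pct_correct_laser = pc[[2]],
               stringsAsFactors = FALSE)
  }))
  beh_test <- lapply(split(behavior, behavior$genotype), function(bg) {
    if (nrow(bg) < 2) return(NULL)
    two_sample_test(bg$pct_correct_pre, bg$pct_correct_laser, "paired_t")
  })
  structure(list(roc = roc, interaction = interaction, profile = profile,
                 behavior = behavior, behavior_test = beh_test,
                 config = config),
            class = "opto_report")
}
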