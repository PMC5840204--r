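#' Classify a single trial from its lick pattern
#'
#' A response is scored when each of the four consecutive 0.5 s intervals
#' starting at odorant onset contains at least one lick (the criterion the
#' task enforces for reward). Outcomes: Hit = S+ with response, Miss = S+
#' without, FA = S- with response, CR = S- without.
#'
#' @param odorant_onset_s Odorant onset, seconds.
#' @param odorant_valence `"Splus"` or `"Sminus"`.
#' @param lick_times_s Numeric vector of lick times (seconds, same time base).
#' @return Character scalar: `"Hit"`, `"Miss"`, `"CR"` or `"FA"`.
#' @export
classify_trial <- function(odorant_onset_s, odorant_valence, lick_times_s) {
  if (is.na(odorant_onset_s)) stop("odorant_onset_s is missing", call. = FALSE)
  if (!odorant_valence %in% c("Splus", "Sminus")) {
    stop("odorant_valence must be 'Splus' or 'Sminus'", call. = FALSE)
  }
  response <- all(vapply(0:3, function(k) {
    a <- odorant_onset_s + 0.5 * k
    any(lick_times_s >= a & lick_times_s < a + 0.5)
  }, logical(1)))
  if (odorant_valence == "Splus") {
    if (response) "Hit" else "Miss"
  } else {
    if (response) "FA" else "CR"
  }
}

#' Classify all trials of a session
#'
#' @param bundle A [session_bundle()], or a trial data.frame (then `licks`
#'   must be given).
#' @param licks Lick table (`trial_index`, `time_s`) when `bundle` is a
#'   data.frame.
#' @return Outcome table: `trial_index`, `odorant_valence`, `response`
#'   (logical), `outcome`, `correct` (Hit or CR).
#' @export
classify_trials <- function(bundle, licks = NULL) {
  if (inherits(bundle, "session_bundle")) {
    trials <- bundle$trials; licks <- bundle$licks
  } else {
    trials <- bundle
    if (is.null(licks)) stop("licks table required", call. = FALSE)
  }
  outcome <- vapply(seq_len(nrow(trials)), function(i) {
    lt <- licks$time_s[licks$trial_index == trials$trial_index[i]]
    classify_trial(trials$odorant_onset_s[i], trials$odorant_valence[i], lt)
  }, character(1))
  data.frame(
    trial_index = trials$trial_index,
    odorant_valence = trials$odorant_valence,
    response = outcome %in% c("Hit", "FA"),
    outcome = outcome,
    correct = outcome %in% c("Hit", "CR"),
    stringsAsFactors = FALSE
  )
}

#' Sliding percent correct
#'
#' Percent of correct trials (Hits + CRs) in a trailing window, reported from
#' the first trial where a full window is available.
#'
#' @param outcomes Outcome table from [classify_trials()].
#' @param window Window length in trials (default 20, the task's block size).
#' @return Data.frame `trial_index`, `percent_correct`.
#' @export
sliding_percent_correct <- function(outcomes, window = 20L) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- nrow(outcomes)
  if (n < window) stop("need at least ", window, " trials", call. = FALSE)
  cs <- cumsum(outcomes$correct)
  idx <- window:n
  counts <- cs[idx] - c(0, cs)[idx - window + 1]
  data.frame(trial_index = outcomes$trial_index[idx],
             percent_correct = 100 * counts / window)
}

#' Block-wise percent correct
#'
#' Percent correct in consecutive disjoint blocks (the task is scored in
#' 20-trial blocks of 10 S+ and 10 S-).
#'
#' @inheritParams sliding_percent_correct
#' @param block Block length in trials.
#' @return Data.frame `block`, `trial_from`, `trial_to`, `percent_correct`.
#' @export
blockwise_percent_correct <- function(outcomes, block = 20L) {
  n <- nrow(outcomes)
  g <- factor((seq_len(n) - 1) %/% block)
  parts <- split(seq_len(n), g)
  do.call(rbind, lapply(seq_along(parts), function(b) {
    i <- parts[[b]]
    data.frame(block = b,
               trial_from = outcomes$trial_index[min(i)],
               trial_to = outcomes$trial_index[max(i)],
               percent_correct = 100 * mean(outcomes$correct[i]))
  }))
}

#' Has the mouse reached the learning criterion?
#'
#' Criterion: at least 80% correct over the final 40 trials in at least two
#' sessions. Sessions with fewer than 40 trials are skipped with a warning.
#'
#' @param outcome_tables List of outcome tables, one per session, in session
#'   order.
#' @param percent Criterion percent (default 80).
#' @param last_n Number of final trials scored (default 40).
#' @param min_sessions Number of qualifying sessions required (default 2).
#' @return Logical scalar.
#' @export
reached_criterion <- function(outcome_tables, percent = 80, last_n = 40L,
                              min_sessions = 2L) {
  ok <- vapply(seq_along(outcome_tables), function(i) {
    ot <- outcome_tables[[i]]
    if (nrow(ot) < last_n) {
      warning("session ", i, " has ", nrow(ot), " < ", last_n,
              " trials; skipped", call. = FALSE)
      return(FALSE)
    }
    tail_correct <- ot$correct[(nrow(ot) - last_n + 1):nrow(ot)]
    100 * mean(tail_correct) >= percent
  }, logical(1))
  sum(ok) >= min_sessions
}

#' Select an analysis epoch across sessions
#'
#' * `naive`: first `n_trials` of the first session.
#' * `proficient`: last `n_trials` of the last session.
#' * `pre_laser`: last `n_trials` of the last session without laser.
#' * `laser`: first `n_trials` of the first session with laser.
#'
#' @param sessions List of [session_bundle()] objects in session order.
#' @param label Epoch label.
#' @param n_trials Number of trials requested; a session shorter than this is
#'   an error (no silent truncation).
#' @return List with `label`, `session` (position in `sessions`),
#'   `trial_indices` (contiguous), `n_trials`.
#' @export
select_epoch <- function(sessions, label = c("naive", "proficient",
                                             "pre_laser", "laser"),
                         n_trials = 30L) {
  label <- match.arg(label)
  laser <- vapply(sessions, function(s) isTRUE(s$meta$laser_enabled), logical(1))
  si <- switch(label,
    naive = 1L,
    proficient = length(sessions),
    pre_laser = { w <- which(!laser); if (!length(w))
      stop("no session without laser", call. = FALSE); max(w) },
    laser = { w <- which(laser); if (!length(w))
      stop("no session with laser", call. = FALSE); min(w) })
  nt <- nrow(sessions[[si]]$trials)
  if (nt < n_trials) {
    stop("epoch '", label, "': session ", si, " has ", nt, " < ", n_trials,
         " trials", call. = FALSE)
  }
  idx <- if (label %in% c("naive", "laser")) seq_len(n_trials)
         else (nt - n_trials + 1):nt
  list(label = label, session = si,
       trial_indices = sessions[[si]]$trials$trial_index[idx],
       n_trials = n_trials)
}
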