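#' Session metadata
#'
#' Construct and validate the metadata block of a go/no-go recording session.
#'
#' @param mouse_id Character scalar identifying the animal.
#' @param genotype `"control"` (driver line only) or `"opsin"` (driver line
#'   expressing the inhibitory opsin in noradrenergic neurons).
#' @param odorant_pair Label for the odorant pair (e.g. `"IAMO"`, `"APEB"`,
#'   `"EAPA"`). The two odorants of a pair are referred to as `"A"` and `"B"`.
#' @param session_index Positive integer; sessions of one mouse are ordered by
#'   this index.
#' @param sampling_rate_hz Sampling rate of the LFP in Hz. Must exceed twice
#'   the highest analysis frequency (effective minimum 200 Hz).
#' @param n_electrodes Number of electrodes (rows of the LFP matrix).
#' @param laser_enabled Logical: was the laser on in this session?
#' @param reward_mapping Which odorant of the pair is rewarded (S+): `"A"` or
#'   `"B"`. Reversal sessions differ from forward sessions in this field.
#' @return An object of class `session_meta` (a named list).
#' @export
session_meta <- function(mouse_id, genotype = c("control", "opsin"),
                         odorant_pair = "APEB", session_index = 1L,
                         sampling_rate_hz = 1000, n_electrodes = 16L,
                         laser_enabled = FALSE, reward_mapping = c("A", "B")) {
  genotype <- match.arg(genotype)
  reward_mapping <- match.arg(reward_mapping)
  meta <- structure(list(
    mouse_id = as.character(mouse_id)[1],
    genotype = genotype,
    odorant_pair = as.character(odorant_pair)[1],
    session_index = as.integer(session_index)[1],
    sampling_rate_hz = as.numeric(sampling_rate_hz)[1],
    n_electrodes = as.integer(n_electrodes)[1],
    laser_enabled = isTRUE(laser_enabled),
    reward_mapping = reward_mapping
  ), class = "session_meta")
  validate_session_meta(meta)
  meta
}

validate_session_meta <- function(meta) {
  if (!nzchar(meta$mouse_id)) stop("meta$mouse_id: must be non-empty", call. = FALSE)
  if (!meta$genotype %in% c("control", "opsin")) {
    stop("meta$genotype: must be 'control' or 'opsin'", call. = FALSE)
  }
  if (is.na(meta$session_index) || meta$session_index < 1) {
    stop("meta$session_index: must be a positive integer", call. = FALSE)
  }
  if (is.na(meta$sampling_rate_hz) || meta$sampling_rate_hz < 200) {
    stop("meta$sampling_rate_hz: must be >= 200 Hz (twice the highest analysis frequency)",
         call. = FALSE)
  }
  if (is.na(meta$n_electrodes) || meta$n_electrodes < 1) {
    stop("meta$n_electrodes: must be >= 1", call. = FALSE)
  }
  if (!meta$reward_mapping %in% c("A", "B")) {
    stop("meta$reward_mapping: must be 'A' or 'B'", call. = FALSE)
  }
  invisible(meta)
}

#' Continuous multi-electrode LFP record
#'
#' @param signal Numeric matrix `[n_electrodes x n_samples]`, microvolts.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param t0 Time of the first sample, seconds. All event times in a session
#'   share this time base.
#' @return An object of class `lfp_record`.
#' @export
lfp_record <- function(signal, sampling_rate_hz, t0 = 0) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (!all(is.finite(signal))) stop("lfp$signal: non-finite values", call. = FALSE)
  structure(list(
    signal = signal,
    sampling_rate_hz = as.numeric(sampling_rate_hz)[1],
    t0 = as.numeric(t0)[1]
  ), class = "lfp_record")
}

lfp_duration_s <- function(lfp) ncol(lfp$signal) / lfp$sampling_rate_hz

lfp_time_range <- function(lfp) c(lfp$t0, lfp$t0 + lfp_duration_s(lfp))

#' Assemble a session bundle
#'
#' A `session_bundle` is the in-memory unit every analysis consumes: metadata,
#' continuous LFP, a per-trial event table, and a long-format lick table.
#'
#' @param meta A [session_meta()].
#' @param lfp An [lfp_record()].
#' @param trials A data.frame with columns `trial_index`, `port_entry_s`,
#'   `odorant_onset_s`, `odorant_valence` (`"Splus"`/`"Sminus"`),
#'   `odorant_duration_s`, `laser_on_s`, `laser_off_s` (NA when the laser is
#'   off), and optionally `outcome` (`"Hit"`, `"Miss"`, `"CR"`, `"FA"`).
#' @param licks A data.frame with columns `trial_index`, `time_s` (one row per
#'   lick, seconds on the LFP time base).
#' @param validate Run [validate_session_bundle()] (default `TRUE`).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(meta, lfp, trials, licks = NULL, validate = TRUE) {
  if (is.null(licks)) {
    licks <- data.frame(trial_index = integer(), time_s = numeric())
  }
  trials <- as.data.frame(trials)
  licks <- as.data.frame(licks)
  if (!"outcome" %in% names(trials)) trials$outcome <- NA_character_
  if (!"laser_on_s" %in% names(trials)) trials$laser_on_s <- NA_real_
  if (!"laser_off_s" %in% names(trials)) trials$laser_off_s <- NA_real_
  bundle <- structure(list(meta = meta, lfp = lfp, trials = trials, licks = licks),
                      class = "session_bundle")
  if (validate) validate_session_bundle(bundle)
  bundle
}

#' Validate a session bundle
#'
#' Checks every structural invariant of the session data model and fails with
#' an error naming the offending field.
#'
#' @param bundle A [session_bundle()].
#' @return The bundle, invisibly, if valid.
#' @export
validate_session_bundle <- function(bundle) {
  validate_session_meta(bundle$meta)
  lfp <- bundle$lfp
  trials <- bundle$trials
  licks <- bundle$licks
  if (nrow(lfp$signal) != bundle$meta$n_electrodes) {
    stop("lfp$signal: ", nrow(lfp$signal), " rows but meta$n_electrodes = ",
         bundle$meta$n_electrodes, call. = FALSE)
  }
  if (!isTRUE(all.equal(lfp$sampling_rate_hz, bundle$meta$sampling_rate_hz))) {
    stop("lfp$sampling_rate_hz: does not match meta$sampling_rate_hz", call. = FALSE)
  }
  need <- c("trial_index", "port_entry_s", "odorant_onset_s", "odorant_valence",
            "odorant_duration_s")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials: missing column(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(trials$trial_index)) {
    stop("trials$trial_index: duplicated values", call. = FALSE)
  }
  if (!all(trials$odorant_valence %in% c("Splus", "Sminus"))) {
    stop("trials$odorant_valence: values must be 'Splus' or 'Sminus'", call. = FALSE)
  }
  if (is.unsorted(trials$odorant_onset_s, strictly = TRUE)) {
    stop("trials$odorant_onset_s: trials must be sorted by onset", call. = FALSE)
  }
  if (any(trials$odorant_onset_s <= trials$port_entry_s)) {
    stop("trials$odorant_onset_s: must be after port_entry_s", call. = FALSE)
  }
  tr <- lfp_time_range(lfp)
  if (any(trials$port_entry_s < tr[1]) ||
      any(trials$odorant_onset_s + trials$odorant_duration_s > tr[2])) {
    stop("trials: trial window outside the LFP record [", tr[1], ", ", tr[2], "] s",
         call. = FALSE)
  }
  las <- !is.na(trials$laser_on_s)
  if (any(las != !is.na(trials$laser_off_s))) {
    stop("trials$laser_off_s: laser_on_s and laser_off_s must be both set or both NA",
         call. = FALSE)
  }
  if (any(las) && any(trials$laser_off_s[las] <= trials$laser_on_s[las])) {
    stop("trials$laser_off_s: must exceed laser_on_s", call. = FALSE)
  }
  if (nrow(licks)) {
    if (!all(c("trial_index", "time_s") %in% names(licks))) {
      stop("licks: need columns trial_index, time_s", call. = FALSE)
    }
    if (!all(licks$trial_index %in% trials$trial_index)) {
      stop("licks$trial_index: refers to unknown trial", call. = FALSE)
    }
    pe <- trials$port_entry_s[match(licks$trial_index, trials$trial_index)]
    if (any(licks$time_s < pe)) {
      stop("licks$time_s: lick before port_entry_s of its trial", call. = FALSE)
    }
    for (ti in unique(licks$trial_index)) {
      ts <- licks$time_s[licks$trial_index == ti]
      if (is.unsorted(ts, strictly = TRUE)) {
        stop("licks$time_s: times within trial ", ti,
             " must be strictly increasing", call. = FALSE)
      }
    }
  }
  invisible(bundle)
}

#' Write a session bundle to disk
#'
#' The on-disk layout is a directory holding `meta.json` (session metadata),
#' `events.csv` (one row per trial), `licks.csv` (`trial_index`, `time_s`),
#' and `lfp.bin` (little-endian float32, electrode-major row order) with an
#' `lfp.json` sidecar describing shape, dtype, `t0` and sampling rate, so the
#' format is self-describing. The signal is stored at float32 precision; a
#' write/read cycle is lossless thereafter (bit-exact binary payload).
#'
#' @param bundle A validated [session_bundle()].
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(bundle, path) {
  validate_session_bundle(bundle)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)

  jsonlite::write_json(unclass(bundle$meta), file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cols <- c("trial_index", "port_entry_s", "odorant_onset_s", "odorant_valence",
            "odorant_duration_s", "laser_on_s", "laser_off_s", "outcome")
  utils::write.csv(bundle$trials[, cols], file.path(path, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$licks, file.path(path, "licks.csv"), row.names = FALSE)

  sig <- bundle$lfp$signal
  con <- file(file.path(path, "lfp.bin"), "wb")
  on.exit(close(con), add = TRUE)
  # electrode-major: all samples of electrode 1, then electrode 2, ...
  writeBin(as.numeric(t(sig)), con, size = 4L, endian = "little")
  jsonlite::write_json(list(
    shape = dim(sig), dtype = "float32", byte_order = "little",
    layout = "electrode_major", t0 = bundle$lfp$t0,
    sampling_rate_hz = bundle$lfp$sampling_rate_hz
  ), file.path(path, "lfp.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. Every file is checked against the sidecar
#' metadata; corruption (truncated binary, shape mismatch, unknown valence
#' token) is reported with the file and field concerned.
#'
#' @param path Directory produced by [write_session()] or conforming to the
#'   documented schema.
#' @return A validated [session_bundle()].
#' @export
read_session <- function(path) {
  need <- c("meta.json", "events.csv", "licks.csv", "lfp.bin", "lfp.json")
  have <- file.exists(file.path(path, need))
  if (!all(have)) {
    stop("missing session file(s): ", paste(need[!have], collapse = ", "),
         " in ", path, call. = FALSE)
  }
  mj <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  meta <- session_meta(mj$mouse_id, mj$genotype, mj$odorant_pair, mj$session_index,
                       mj$sampling_rate_hz, mj$n_electrodes, mj$laser_enabled,
                       mj$reward_mapping)

  lj <- jsonlite::read_json(file.path(path, "lfp.json"), simplifyVector = TRUE)
  if (!identical(lj$dtype, "float32")) {
    stop("lfp.json: unsupported dtype '", lj$dtype, "'", call. = FALSE)
  }
  n_el <- as.integer(lj$shape[1]); n_samp <- as.integer(lj$shape[2])
  sz <- file.info(file.path(path, "lfp.bin"))$size
  if (sz != 4 * n_el * n_samp) {
    stop("lfp.bin: ", sz, " bytes but lfp.json shape [", n_el, ", ", n_samp,
         "] implies ", 4 * n_el * n_samp, call. = FALSE)
  }
  con <- file(file.path(path, "lfp.bin"), "rb")
  raw <- readBin(con, what = "numeric", n = n_el * n_samp, size = 4L,
                 endian = "little")
  close(con)
  sig <- matrix(raw, nrow = n_el, byrow = TRUE)
  lfp <- lfp_record(sig, lj$sampling_rate_hz, lj$t0)

  trials <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  bad <- which(!trials$odorant_valence %in% c("Splus", "Sminus"))
  if (length(bad)) {
    stop("events.csv: unknown odorant_valence '", trials$odorant_valence[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  }
  if ("outcome" %in% names(trials)) {
    trials$outcome <- as.character(trials$outcome)
    trials$outcome[trials$outcome == ""] <- NA_character_
  }
  licks <- utils::read.csv(file.path(path, "licks.csv"), stringsAsFactors = FALSE)
  session_bundle(meta, lfp, trials, licks)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> mouse %s, %s, pair %s, session %d%s\n",
              x$meta$mouse_id, x$meta$genotype, x$meta$odorant_pair,
              x$meta$session_index,
              if (x$meta$laser_enabled) " [laser]" else ""))
  cat(sprintf("  %d electrodes x %d samples @ %g Hz (%.1f s), %d trials, %d licks\n",
              nrow(x$lfp$signal), ncol(x$lfp$signal), x$lfp$sampling_rate_hz,
              lfp_duration_s(x$lfp), nrow(x$trials), nrow(x$licks)))
  invisible(x)
}
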