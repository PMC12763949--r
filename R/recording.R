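#' Trial labels and follow-up times
#'
#' Each session comprises one baseline trial (`pre`) and seven follow-up
#' trials recorded every 5 minutes over a 30-minute window. `follow_up_min`
#' is the nominal time since the end of the intervention/rest period:
#' `post` is 0 min, `post5` 5 min, ..., `post30` 30 min; the baseline has no
#' follow-up time (`NA`).
#'
#' @format Named integer vector mapping trial label to follow-up minutes.
#' @export
trial_schedule <- c(
  pre = NA_integer_, post = 0L, post5 = 5L, post10 = 10L,
  post15 = 15L, post20 = 20L, post25 = 25L, post30 = 30L
)

sessions <- c("control", "fmv")

#' Construct a single-trial recording
#'
#' Bundles one trial's synchronized raw surface-EMG and elbow joint-angle
#' (range-of-motion, ROM) streams with its study metadata. Both streams share
#' one timeline: sample `i` of `emg` and of `rom` were acquired at time
#' `(i - 1) / fs_hz` seconds from trial start.
#'
#' @param emg numeric vector of raw sEMG samples, in microvolts.
#' @param rom numeric vector of joint angles, in degrees; same length as `emg`.
#' @param fs_hz sampling rate in Hz (protocol default 1024).
#' @param participant_id participant identifier string.
#' @param session `"control"` or `"fmv"`.
#' @param trial_label one of `names(trial_schedule)`.
#' @param expected_duration_s nominal trial duration; deviations beyond
#'   `duration_tol_s` raise a warning (trials shorter than 10 s are rejected).
#' @param duration_tol_s tolerance on the nominal duration, in seconds.
#' @return An object of class `emg_recording`.
#' @export
recording <- function(emg, rom, fs_hz = 1024, participant_id = "P01",
                      session = "control", trial_label = "pre",
                      expected_duration_s = 60, duration_tol_s = 10) {
  if (!is.numeric(emg) || !is.numeric(rom)) data_error("emg and rom must be numeric")
  if (length(emg) == 0L) data_error("empty trial: no samples")
  if (length(emg) != length(rom)) {
    data_error(sprintf("emg (%d) and rom (%d) must have the same length",
                       length(emg), length(rom)))
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    parameter_error("fs_hz must be a positive scalar")
  }
  if (anyNA(emg) || any(!is.finite(emg))) {
    data_error(sprintf("emg contains non-finite values (first at sample %d)",
                       which(!is.finite(emg))[1]))
  }
  session <- match.arg(session, sessions)
  trial_label <- match.arg(trial_label, names(trial_schedule))
  dur <- length(emg) / fs_hz
  if (dur < 10) data_error(sprintf("trial too short: %.2f s (minimum 10 s)", dur))
  if (abs(dur - expected_duration_s) > duration_tol_s) {
    warning(sprintf("trial duration %.1f s deviates from nominal %.1f s",
                    dur, expected_duration_s), call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id), session = session,
         trial_label = trial_label,
         follow_up_min = unname(trial_schedule[trial_label]),
         fs_hz = as.numeric(fs_hz), emg = as.numeric(emg), rom = as.numeric(rom)),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s / %s / %s: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$session, x$trial_label,
              length(x$emg), x$fs_hz, length(x$emg) / x$fs_hz))
  invisible(x)
}

#' Read one trial from a CSV file
#'
#' The file must be comma-separated with a header row containing the columns
#' `time_s`, `emg_uV` and `rom_deg` ('.' decimal, UTF-8). The sampling rate is
#' inferred as the reciprocal of the median time step, rounded to the nearest
#' integer Hz, unless `fs_hz` is supplied.
#'
#' @param path CSV file path.
#' @param participant_id,session,trial_label trial metadata (see [recording()]).
#' @param fs_hz optional sampling-rate override in Hz.
#' @param ... passed to [recording()].
#' @return An `emg_recording`.
#' @export
read_trial <- function(path, participant_id = "P01", session = "control",
                       trial_label = "pre", fs_hz = NULL, ...) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = TRUE)
  required <- c("time_s", "emg_uV", "rom_deg")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    format_error(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  tm <- dt[["time_s"]]
  if (nrow(dt) == 0L) data_error(sprintf("empty trial file: %s", path))
  if (anyNA(dt[["emg_uV"]]) || any(!is.finite(dt[["emg_uV"]]))) {
    data_error(sprintf("non-finite emg_uV value at row %d of %s",
                       which(!is.finite(dt[["emg_uV"]]))[1], path))
  }
  if (nrow(dt) > 1L) {
    dts <- diff(tm)
    if (any(dts <= 0)) {
      data_error(sprintf("non-monotonic time_s at row %d of %s",
                         which(dts <= 0)[1] + 1L, path))
    }
    if (is.null(fs_hz)) fs_hz <- round(1 / stats::median(dts))
  } else if (is.null(fs_hz)) {
    data_error("cannot infer sampling rate from a single row; supply fs_hz")
  }
  recording(emg = dt[["emg_uV"]], rom = dt[["rom_deg"]], fs_hz = fs_hz,
            participant_id = participant_id, session = session,
            trial_label = trial_label, ...)
}

#' Write one trial to a CSV file
#'
#' Writes the `time_s, emg_uV, rom_deg` format read by [read_trial()].
#' Re-reading reproduces the signals to full double precision.
#'
#' @param rec an `emg_recording`.
#' @param path output CSV path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  n <- length(rec$emg)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) / rec$fs_hz,
    emg_uV = rec$emg, rom_deg = rec$rom)
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = ",", dec = ".")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) vibremg_error(sprintf("cannot write trial file: %s", path),
                         "vibremg_io_error")
  invisible(path)
}

#' Construct a session manifest
#'
#' A manifest lists one participant-session's trials in follow-up order:
#' exactly one `pre` trial plus post trials strictly ordered by follow-up
#' time, with no duplicate labels. `trials` maps trial label to either a file
#' path (relative to the session directory) or an in-memory `emg_recording`.
#'
#' @param participant_id,session metadata (see [recording()]).
#' @param trials named list or character vector, names in `names(trial_schedule)`.
#' @param metadata optional free-form list (date, device notes).
#' @return An object of class `session_manifest`.
#' @export
session_manifest <- function(participant_id, session, trials, metadata = list()) {
  session <- match.arg(session, sessions)
  labels <- names(trials)
  if (is.null(labels) || anyNA(labels) || any(labels == "")) {
    manifest_error("trials must be named by trial label")
  }
  if (anyDuplicated(labels)) {
    manifest_error(sprintf("duplicate trial label(s): %s",
                           paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  unknown <- setdiff(labels, names(trial_schedule))
  if (length(unknown)) {
    manifest_error(sprintf("unknown trial label(s): %s", paste(unknown, collapse = ", ")))
  }
  if (sum(labels == "pre") != 1L) manifest_error("manifest must contain exactly one pre trial")
  post <- setdiff(labels, "pre")
  missing_posts <- setdiff(setdiff(names(trial_schedule), "pre"), post)
  if (length(missing_posts)) {
    warning(sprintf("%s/%s: missing post trial(s): %s", participant_id, session,
                    paste(missing_posts, collapse = ", ")), call. = FALSE)
  }
  ord <- c("pre", intersect(setdiff(names(trial_schedule), "pre"), post))
  structure(
    list(participant_id = as.character(participant_id), session = session,
         trials = as.list(trials)[ord], metadata = metadata),
    class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> %s / %s: %d trial(s) [%s]\n",
              x$participant_id, x$session, length(x$trials),
              paste(names(x$trials), collapse = ", ")))
  invisible(x)
}

#' Load a study tree of session manifests
#'
#' Expects the layout `root/<participant>/<session>/manifest.yml`, each
#' manifest a key-value file with a `trials` map of trial label to relative
#' CSV path (the format written by [simulate_study()]). Incomplete sessions
#' are retained with a warning so unbalanced studies flow through to the
#' mixed-model stage.
#'
#' @param root study root directory.
#' @return List of `session_manifest` objects (class `emg_study`).
#' @export
load_study <- function(root) {
  if (!dir.exists(root)) format_error(sprintf("study root not found: %s", root))
  paths <- sort(Sys.glob(file.path(root, "*", "*", "manifest.yml")))
  if (!length(paths)) {
    warning(sprintf("no session manifests found under %s", root), call. = FALSE)
    return(structure(list(), class = "emg_study"))
  }
  manifests <- lapply(paths, function(p) {
    m <- yaml::read_yaml(p)
    trials <- m$trials
    if (anyDuplicated(names(trials))) {
      manifest_error(sprintf("duplicate trial label in %s", p))
    }
    trials <- lapply(trials, function(rel) file.path(dirname(p), rel))
    session_manifest(m$participant_id, m$session, trials,
                     metadata = m$metadata %||% list())
  })
  structure(manifests, class = "emg_study")
}

#' @export
print.emg_study <- function(x, ...) {
  cat(sprintf("<emg_study> %d session manifest(s), %d participant(s)\n",
              length(x), length(unique(vapply(x, `[[`, "", "participant_id")))))
  invisible(x)
}

# Resolve a manifest entry (path or in-memory recording) to an emg_recording.
resolve_trial <- function(manifest, label) {
  entry <- manifest$trials[[label]]
  if (inherits(entry, "emg_recording")) return(entry)
  read_trial(entry, participant_id = manifest$participant_id,
             session = manifest$session, trial_label = label)
}
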