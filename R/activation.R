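#' Detect movement onset from the joint-angle signal
#'
#' Onset is the earliest time at which the absolute angular speed (central
#' difference, lightly smoothed) stays above `speed_thresh_deg_s` for at
#' least `sustain_s` seconds. The joint-angle stream is the only kinematic
#' signal recorded, so it doubles as the movement marker.
#'
#' @param rom joint-angle samples in degrees.
#' @param fs_hz sampling rate in Hz.
#' @param speed_thresh_deg_s angular-speed threshold, degrees per second.
#' @param sustain_s minimum time the speed must stay above threshold.
#' @param smooth_s width of the smoothing window applied to the speed trace.
#' @return Onset time in seconds from trial start. If movement is already
#'   under way at the first sample, 0 is returned with a warning.
#' @export
detect_movement_onset <- function(rom, fs_hz, speed_thresh_deg_s = 5,
                                  sustain_s = 0.5, smooth_s = 0.1) {
  n <- length(rom)
  sustain_n <- max(1L, round(sustain_s * fs_hz))
  if (n < sustain_n + 2L) data_error("rom too short for onset detection")
  speed <- c(0, (rom[3:n] - rom[1:(n - 2)]) * fs_hz / 2, 0)
  # rectify before smoothing so brief speed zero-crossings inside continuous
  # movement do not break the sustained run
  speed <- moving_average(abs(speed), round(smooth_s * fs_hz))
  above <- speed > speed_thresh_deg_s
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= sustain_n)
  if (!length(hit)) onset_error("no movement detected in rom signal")
  onset_idx <- starts[hit[1]]
  if (onset_idx <= 1L) {
    warning("movement under way at trial start; no quiescent lead-in", call. = FALSE)
    return(0)
  }
  (onset_idx - 1L) / fs_hz
}

#' Estimate the baseline-noise activation threshold
#'
#' Implements the resting-noise correction: find the minimum envelope value
#' before movement onset, place a window of up to `window_points` envelope
#' samples around it (half each side, clipped to the pre-onset segment), and
#' set the activation threshold to the window mean plus `k_sd` standard
#' deviations (population SD). Ties in the minimum resolve to the first
#' occurrence.
#'
#' @param env an `emg_envelope`.
#' @param onset_s movement-onset time in seconds (see
#'   [detect_movement_onset()]).
#' @param window_points window size in envelope samples (default 60, i.e.
#'   15 s at the 4 Hz envelope rate).
#' @param k_sd number of standard deviations above the window mean.
#' @return An object of class `activation_threshold` with 0-based envelope
#'   indices `onset_index`, `min_index`, half-open `window_bounds`, and
#'   `noise_mean`, `noise_sd`, `threshold` in µV.
#' @export
estimate_threshold <- function(env, onset_s, window_points = 60, k_sd = 3) {
  stopifnot(inherits(env, "emg_envelope"))
  onset_index <- floor(onset_s * env$fs_env_hz)   # 0-based envelope index
  if (onset_index < 1) threshold_error("no pre-onset segment in envelope")
  onset_index <- min(onset_index, length(env$values))
  pre <- env$values[seq_len(onset_index)]
  min_index <- which.min(pre) - 1L                # 0-based, first occurrence
  half <- floor(window_points / 2)
  a <- max(0L, min_index - half)
  b <- min(onset_index, min_index + half, length(env$values))
  win <- env$values[(a + 1L):b]
  noise_mean <- mean(win)
  noise_sd <- sqrt(mean((win - noise_mean)^2))    # population SD
  structure(
    list(onset_index = onset_index, min_index = min_index,
         window_bounds = c(a, b), noise_mean = noise_mean,
         noise_sd = noise_sd, threshold = noise_mean + k_sd * noise_sd),
    class = "activation_threshold")
}

#' @export
print.activation_threshold <- function(x, ...) {
  cat(sprintf(
    "<activation_threshold> %.3f uV (noise %.3f +/- %.3f uV, window [%d, %d), min at %d)\n",
    x$threshold, x$noise_mean, x$noise_sd,
    x$window_bounds[1], x$window_bounds[2], x$min_index))
  invisible(x)
}

#' Apply an activation threshold to an envelope
#'
#' Subtracts the threshold and keeps only suprathreshold activity: samples
#' above the threshold become `envelope - threshold`, all others become zero.
#' Sub-threshold samples are zeroed but kept on the timeline so cycle windows
#' remain time-aligned.
#'
#' @param env an `emg_envelope`.
#' @param thr an `activation_threshold` (or a single non-negative number).
#' @return An object of class `corrected_envelope` with fields `values`,
#'   `active_mask`, `threshold_used`, plus the envelope timing metadata.
#' @export
apply_threshold <- function(env, thr) {
  stopifnot(inherits(env, "emg_envelope"))
  tval <- if (inherits(thr, "activation_threshold")) thr$threshold else thr
  if (!is.finite(tval) || tval < 0) parameter_error("threshold must be finite and >= 0")
  mask <- env$values > tval
  values <- ifelse(mask, env$values - tval, 0)
  structure(
    list(values = values, active_mask = mask, threshold_used = thr,
         fs_env_hz = env$fs_env_hz, window_s = env$window_s,
         source_fs_hz = env$source_fs_hz),
    class = "corrected_envelope")
}

#' @export
print.corrected_envelope <- function(x, ...) {
  cat(sprintf("<corrected_envelope> %d samples @ %g Hz, %.1f%% active\n",
              length(x$values), x$fs_env_hz, 100 * mean(x$active_mask)))
  invisible(x)
}
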