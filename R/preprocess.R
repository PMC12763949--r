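#' Zero-phase Butterworth band-pass filter
#'
#' Applies the standard sEMG conditioning filter: a Butterworth band-pass
#' (default 20-450 Hz, order 4 per band edge) run forward and backward so the
#' net response is zero-phase and the envelope timeline stays aligned with
#' the joint-angle signal. Edge transients are tamed by reflecting the signal
#' at both ends before filtering.
#'
#' @param x numeric vector of raw sEMG samples.
#' @param fs_hz sampling rate in Hz; must exceed `2 * high_hz`.
#' @param low_hz,high_hz passband corner frequencies in Hz.
#' @param order Butterworth design order (per band edge).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs_hz, low_hz = 20, high_hz = 450, order = 4) {
  if (high_hz >= fs_hz / 2) {
    parameter_error(sprintf("high_hz (%g) must be below Nyquist (%g Hz)",
                            high_hz, fs_hz / 2))
  }
  if (low_hz <= 0 || low_hz >= high_hz) {
    parameter_error("require 0 < low_hz < high_hz")
  }
  pad <- 3L * (2L * order + 1L)
  if (length(x) <= pad) {
    data_error(sprintf("signal too short for filtering: %d samples (need > %d)",
                       length(x), pad))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  # reflect-pad, filter forward then backward, trim
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x,
          2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)])
  y <- .iir_filter(bf$b, bf$a, xp)
  y <- rev(.iir_filter(bf$b, bf$a, rev(y)))
  y[(pad + 1L):(pad + length(x))]
}

#' Full-wave rectification
#'
#' Elementwise absolute value; idempotent.
#'
#' @param x numeric vector.
#' @return `abs(x)`.
#' @export
rectify <- function(x) {
  if (any(!is.finite(x))) data_error("rectify: input contains non-finite values")
  abs(x)
}

#' RMS envelope over non-overlapping windows
#'
#' Partitions the signal into consecutive non-overlapping windows of
#' `window_s` seconds and returns the root-mean-square of each, giving an
#' envelope at `1 / window_s` Hz (4 Hz for the 0.25-s default). A trailing
#' partial window is discarded rather than zero-padded, which would bias the
#' final sample downward.
#'
#' @param x rectified sEMG samples.
#' @param fs_hz raw sampling rate in Hz.
#' @param window_s window length in seconds; `window_s * fs_hz` must round to
#'   at least one sample.
#' @return An object of class `emg_envelope` with fields `values` (µV),
#'   `fs_env_hz`, `window_s`, `source_fs_hz`. Envelope sample `k` (1-based)
#'   summarises raw samples in the half-open window
#'   `[(k-1) * window_s, k * window_s)` seconds.
#' @export
rms_envelope <- function(x, fs_hz, window_s = 0.25) {
  if (length(x) == 0L) data_error("rms_envelope: empty input")
  w <- round(window_s * fs_hz)
  if (w < 1) parameter_error("window_s * fs_hz must round to >= 1 sample")
  n_win <- floor(length(x) / w)
  if (n_win < 1) data_error("rms_envelope: input shorter than one window")
  xs <- x[seq_len(n_win * w)]
  values <- sqrt(colMeans(matrix(xs * xs, nrow = w)))
  structure(
    list(values = values, fs_env_hz = fs_hz / w, window_s = window_s,
         source_fs_hz = fs_hz),
    class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %d samples @ %g Hz (window %g s from %g Hz raw)\n",
              length(x$values), x$fs_env_hz, x$window_s, x$source_fs_hz))
  invisible(x)
}

#' @export
length.emg_envelope <- function(x) length(x$values)
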