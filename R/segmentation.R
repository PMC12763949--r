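#' Detect flexion-extension cycles from the joint-angle signal
#'
#' Cycle boundaries are anchored at successive joint-angle maxima (peak
#' flexion). Peaks are required to be at least half a nominal cycle apart and
#' to have topographic prominence of at least `prominence_frac` of the
#' signal's amplitude range, which rejects jitter peaks at the working
#' cadence. Cycle `i` is the half-open interval from peak `i` to peak `i+1`.
#'
#' @param rom joint-angle samples in degrees.
#' @param fs_hz sampling rate in Hz.
#' @param cadence_bpm nominal movement cadence (beats per minute); one beat
#'   is one full flexion-extension cycle.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   angle range.
#' @param min_prominence_deg absolute prominence floor in degrees; an
#'   oscillation smaller than this is not a joint movement, so a flat or
#'   noise-only angle trace cannot yield cycles.
#' @param min_sep_factor minimum inter-peak distance as a fraction of the
#'   nominal cycle duration.
#' @param smooth_s smoothing window applied before peak picking, seconds.
#' @param anchor `"peak"` (peak flexion, default) or `"valley"` (full
#'   extension); valleys are found as peaks of the negated angle.
#' @return An object of class `cycle_set`: data frame `cycles` with
#'   `start_s`/`end_s` half-open intervals, empty `selected`, and
#'   `cadence_bpm`.
#' @export
detect_cycles <- function(rom, fs_hz, cadence_bpm = 60, prominence_frac = 0.25,
                          min_sep_factor = 0.5, smooth_s = 0.1,
                          min_prominence_deg = 5,
                          anchor = c("peak", "valley")) {
  anchor <- match.arg(anchor)
  x <- moving_average(rom, round(smooth_s * fs_hz))
  if (anchor == "valley") x <- -x
  rng <- diff(range(x))
  cycle_s <- 60 / cadence_bpm
  if (length(rom) / fs_hz < 2 * cycle_s) {
    segmentation_error("rom spans fewer than two nominal cycles")
  }
  peaks <- find_peaks(x, min_distance = round(min_sep_factor * cycle_s * fs_hz),
                      min_prominence = max(prominence_frac * rng,
                                           min_prominence_deg))
  if (length(peaks) < 2L) {
    segmentation_error(sprintf("found %d qualifying peak(s); need at least 2",
                               length(peaks)))
  }
  t_peaks <- (peaks - 1) / fs_hz
  cycles <- data.frame(start_s = t_peaks[-length(t_peaks)], end_s = t_peaks[-1])
  structure(list(cycles = cycles, selected = integer(0),
                 cadence_bpm = cadence_bpm, anchor = anchor),
            class = "cycle_set")
}

#' Select the central consecutive cycles
#'
#' Picks `k` consecutive cycles centred on the middle of the detected
#' sequence (block start `floor((n - k) / 2)`, favouring the earlier block
#' when the centring is ambiguous). Central cycles avoid the transitional
#' movements at the start and end of a trial.
#'
#' @param cs a `cycle_set` from [detect_cycles()].
#' @param k number of consecutive cycles to select (default 10).
#' @return The `cycle_set` with `selected` filled (1-based cycle indices).
#' @export
select_central <- function(cs, k = 10) {
  stopifnot(inherits(cs, "cycle_set"))
  n <- nrow(cs$cycles)
  if (n < k) {
    selection_error(sprintf("only %d cycle(s) detected; %d required", n, k))
  }
  start <- floor((n - k) / 2)
  cs$selected <- seq.int(start + 1L, start + k)
  cs
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycle(s) at nominal %g bpm (%s-anchored)",
              nrow(x$cycles), x$cadence_bpm, x$anchor))
  if (length(x$selected)) {
    cat(sprintf("; selected %d..%d", min(x$selected), max(x$selected)))
  }
  cat("\n")
  invisible(x)
}

# Time span (s) of the selected block, half-open.
selected_span <- function(cs) {
  if (!length(cs$selected)) metric_error("no cycles selected")
  c(cs$cycles$start_s[min(cs$selected)], cs$cycles$end_s[max(cs$selected)])
}
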