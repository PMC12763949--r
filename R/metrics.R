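#' Total RMS over the selected movement cycles
#'
#' Pools every corrected-envelope sample whose window start falls inside the
#' union of the selected cycle intervals and returns the RMS of those values.
#' Samples zeroed by the activation threshold stay in the pool, so the
#' statistic remains an energy measure over the full task window; set
#' `pooling = "active_only"` to restrict to suprathreshold samples, or
#' `pooling = "per_cycle_mean"` to average per-cycle RMS values instead.
#'
#' @param cenv a `corrected_envelope`.
#' @param cs a `cycle_set` with a non-empty selection.
#' @param pooling `"pooled"` (default), `"active_only"`, or `"per_cycle_mean"`.
#' @return Total RMS in µV.
#' @export
total_rms <- function(cenv, cs, pooling = c("pooled", "active_only", "per_cycle_mean")) {
  stopifnot(inherits(cenv, "corrected_envelope"), inherits(cs, "cycle_set"))
  pooling <- match.arg(pooling)
  t_env <- (seq_along(cenv$values) - 1) / cenv$fs_env_hz
  if (pooling == "per_cycle_mean") {
    vals <- vapply(cs$selected, function(i) {
      idx <- t_env >= cs$cycles$start_s[i] & t_env < cs$cycles$end_s[i]
      if (!any(idx)) metric_error("cycle contains no envelope samples")
      sqrt(mean(cenv$values[idx]^2))
    }, numeric(1))
    return(mean(vals))
  }
  span <- selected_span(cs)
  idx <- t_env >= span[1] & t_env < span[2]
  if (pooling == "active_only") idx <- idx & cenv$active_mask
  if (!any(idx)) metric_error("no envelope samples in selected cycle span")
  sqrt(mean(cenv$values[idx]^2))
}

#' Post/pre RMS ratio
#'
#' The modulation statistic: a follow-up trial's total RMS divided by the
#' same session's baseline total RMS. Unit-free, 1 means no change.
#'
#' @param pre_rms baseline trial RMS in µV; must be positive.
#' @param post_rms follow-up trial RMS in µV.
#' @return `post_rms / pre_rms`.
#' @export
compute_ratio <- function(pre_rms, post_rms) {
  if (!is.finite(pre_rms) || pre_rms <= 0) {
    ratio_error("baseline RMS must be positive to form a post/pre ratio")
  }
  post_rms / pre_rms
}

#' Assemble the long-format ratio table
#'
#' Joins each participant-session's follow-up RMS values to its baseline and
#' computes post/pre ratios. Missing follow-up trials simply yield missing
#' rows; participant-sessions without a usable baseline are dropped with a
#' warning, mirroring the unbalanced-data tolerance of the mixed model.
#'
#' @param trial_rms data frame with columns `participant_id`, `session`,
#'   `trial_label`, `rms` (one row per processed trial).
#' @return A `ratio_table` data frame with columns `participant_id`,
#'   `session`, `follow_up_min`, `pre_rms_uv`, `post_rms_uv`, `ratio`.
#' @export
build_ratio_table <- function(trial_rms) {
  required <- c("participant_id", "session", "trial_label", "rms")
  if (!all(required %in% names(trial_rms))) {
    format_error(sprintf("trial_rms must have columns: %s",
                         paste(required, collapse = ", ")))
  }
  dt <- data.table::as.data.table(trial_rms)
  pre <- dt[dt$trial_label == "pre", ]
  post <- dt[dt$trial_label != "pre", ]
  rows <- list()
  for (i in seq_len(nrow(post))) {
    p <- post[i, ]
    base <- pre[pre$participant_id == p$participant_id & pre$session == p$session, ]
    if (nrow(base) == 0L) next
    if (!is.finite(base$rms) || base$rms <= 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = p$participant_id, session = p$session,
      follow_up_min = unname(trial_schedule[p$trial_label]),
      pre_rms_uv = base$rms, post_rms_uv = p$rms,
      ratio = p$rms / base$rms, stringsAsFactors = FALSE)
  }
  # warn about participant-sessions lacking a usable baseline
  key <- function(d) paste(d$participant_id, d$session)
  bad_pre <- unique(key(post)[!(key(post) %in% key(pre[is.finite(pre$rms) & pre$rms > 0, ]))])
  if (length(bad_pre)) {
    warning(sprintf("excluded participant-session(s) without usable baseline: %s",
                    paste(bad_pre, collapse = "; ")), call. = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(participant_id = character(), session = character(),
               follow_up_min = integer(), pre_rms_uv = numeric(),
               post_rms_uv = numeric(), ratio = numeric())
  }
  out <- out[order(out$participant_id, out$session, out$follow_up_min), ]
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Write a ratio table as CSV
#' @param rt a `ratio_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(rt, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(rt), path)
  invisible(path)
}

#' Read a ratio table written by [write_ratio_table()]
#' @param path CSV path.
#' @return A `ratio_table`.
#' @export
read_ratio_table <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  class(out) <- c("ratio_table", "data.frame")
  out
}
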