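#' Pipeline configuration
#'
#' All tunable parameters of the processing and statistics stages in one
#' list. The defaults reproduce the protocol's stated settings: 20-450 Hz
#' order-4 Butterworth band-pass, 0.25-s non-overlapping RMS windows (4 Hz
#' envelope), 60-point noise window with a mean + 3 SD threshold, 10 central
#' cycles, and alpha = 0.05 throughout.
#'
#' @param low_hz,high_hz,filter_order band-pass settings.
#' @param window_s RMS envelope window, seconds.
#' @param window_points activation-threshold noise window, envelope samples.
#' @param k_sd threshold = noise mean + `k_sd` * noise SD.
#' @param speed_thresh_deg_s,sustain_s movement-onset criterion.
#' @param k_cycles number of central cycles per trial.
#' @param cadence_bpm nominal movement cadence.
#' @param prominence_frac,min_sep_factor cycle peak-detection settings.
#' @param cycle_anchor `"peak"` or `"valley"` cycle boundaries.
#' @param rms_pooling `"pooled"`, `"active_only"` or `"per_cycle_mean"`.
#' @param lmm_scale `"log"` or `"raw"` intragroup model scale.
#' @param df_method `"wald"` or `"satterthwaite"` intragroup tests.
#' @param alpha significance level for reporting.
#' @param alpha_normality Shapiro-Wilk gate level for the paired tests.
#' @param seed seed used when the pipeline itself simulates data.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(low_hz = 20, high_hz = 450, filter_order = 4,
                            window_s = 0.25, window_points = 60, k_sd = 3,
                            speed_thresh_deg_s = 5, sustain_s = 0.5,
                            k_cycles = 10, cadence_bpm = 60,
                            prominence_frac = 0.25, min_sep_factor = 0.5,
                            cycle_anchor = "peak", rms_pooling = "pooled",
                            lmm_scale = "log", df_method = "wald",
                            alpha = 0.05, alpha_normality = 0.05,
                            seed = 20260101) {
  structure(
    list(low_hz = low_hz, high_hz = high_hz, filter_order = filter_order,
         window_s = window_s, window_points = window_points, k_sd = k_sd,
         speed_thresh_deg_s = speed_thresh_deg_s, sustain_s = sustain_s,
         k_cycles = k_cycles, cadence_bpm = cadence_bpm,
         prominence_frac = prominence_frac, min_sep_factor = min_sep_factor,
         cycle_anchor = cycle_anchor, rms_pooling = rms_pooling,
         lmm_scale = lmm_scale, df_method = df_method, alpha = alpha,
         alpha_normality = alpha_normality, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through a human-readable YAML file.
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @param config a `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Process one recording through the full signal chain
#'
#' Band-pass filter, rectify, RMS envelope, movement-onset detection,
#' baseline-noise threshold, cycle segmentation, central-cycle selection,
#' total RMS.
#'
#' @param rec an `emg_recording`.
#' @param config a `pipeline_config`.
#' @return List with `rms` (µV) plus QC fields: `onset_s`, `threshold`
#'   (`activation_threshold`), `n_cycles`, `selected` (index range).
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  filt <- bandpass_filter(rec$emg, rec$fs_hz, config$low_hz, config$high_hz,
                          config$filter_order)
  env <- rms_envelope(rectify(filt), rec$fs_hz, config$window_s)
  onset_s <- detect_movement_onset(rec$rom, rec$fs_hz,
                                   config$speed_thresh_deg_s, config$sustain_s)
  thr <- estimate_threshold(env, onset_s, config$window_points, config$k_sd)
  cenv <- apply_threshold(env, thr)
  cycles <- select_central(
    detect_cycles(rec$rom, rec$fs_hz, config$cadence_bpm,
                  config$prominence_frac, config$min_sep_factor,
                  anchor = config$cycle_anchor),
    config$k_cycles)
  list(rms = total_rms(cenv, cycles, config$rms_pooling),
       onset_s = onset_s, threshold = thr,
       n_cycles = nrow(cycles$cycles), selected = range(cycles$selected))
}

#' Process a study into a ratio table
#'
#' Runs [process_recording()] over every trial of every session manifest.
#' Per-trial failures are recorded in the QC log and the pipeline continues
#' over the remaining trials, so unbalanced data reach the mixed model
#' rather than aborting the run.
#'
#' @param study an `emg_study` ([load_study()] or [simulate_study()]).
#' @param config a `pipeline_config`.
#' @return List with `ratios` (a `ratio_table`) and `qc` (one row per trial:
#'   onset, threshold, cycle count, selected block, status).
#' @export
run_process <- function(study, config = pipeline_config()) {
  qc <- list()
  rms_rows <- list()
  for (m in study) {
    for (lab in names(m$trials)) {
      res <- tryCatch({
        rec <- resolve_trial(m, lab)
        pr <- process_recording(rec, config)
        rms_rows[[length(rms_rows) + 1L]] <- data.frame(
          participant_id = m$participant_id, session = m$session,
          trial_label = lab, rms = pr$rms, stringsAsFactors = FALSE)
        data.frame(participant_id = m$participant_id, session = m$session,
                   trial_label = lab, status = "ok", onset_s = pr$onset_s,
                   threshold_uv = pr$threshold$threshold,
                   n_cycles = pr$n_cycles,
                   selected_first = pr$selected[1], selected_last = pr$selected[2],
                   rms_uv = pr$rms, message = "", stringsAsFactors = FALSE)
      }, vibremg_error = function(e) {
        data.frame(participant_id = m$participant_id, session = m$session,
                   trial_label = lab, status = "failed", onset_s = NA_real_,
                   threshold_uv = NA_real_, n_cycles = NA_integer_,
                   selected_first = NA_integer_, selected_last = NA_integer_,
                   rms_uv = NA_real_, message = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      qc[[length(qc) + 1L]] <- res
    }
  }
  qc <- do.call(rbind, qc)
  n_failed <- sum(qc$status == "failed")
  if (n_failed > 0) {
    warning(sprintf("%d trial(s) failed processing; see the QC log", n_failed),
            call. = FALSE)
  }
  trial_rms <- if (length(rms_rows)) do.call(rbind, rms_rows) else {
    data.frame(participant_id = character(), session = character(),
               trial_label = character(), rms = numeric())
  }
  list(ratios = build_ratio_table(trial_rms), qc = qc)
}

#' Run the statistical stage over a ratio table
#'
#' @param ratios a `ratio_table`.
#' @param config a `pipeline_config`.
#' @return A `stats_report`.
#' @export
run_stats <- function(ratios, config = pipeline_config()) {
  if (nrow(as.data.frame(ratios)) == 0L) data_error("empty ratio table")
  stats_report(ratios, scale = config$lmm_scale, df_method = config$df_method,
               alpha_normality = config$alpha_normality)
}

#' End-to-end run: simulate (or ingest), process, analyse, report
#'
#' @param config a `pipeline_config`.
#' @param study optional `emg_study` or study root directory; if omitted, a
#'   default synthetic study is generated with `sim_config(seed = config$seed)`.
#' @param out_dir optional output directory; when given, writes `ratios.csv`,
#'   `qc.csv`, the stats-report CSVs, `boxplot.png` (when a graphics device
#'   is available) and a `provenance.yml` capturing the configuration and
#'   seed.
#' @return List with `ratios`, `qc`, `report`.
#' @export
run_all <- function(config = pipeline_config(), study = NULL, out_dir = NULL) {
  if (is.null(study)) {
    study <- simulate_study(sim_config(seed = config$seed))
  } else if (is.character(study)) {
    study <- load_study(study)
  }
  processed <- run_process(study, config)
  report <- run_stats(processed$ratios, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ratio_table(processed$ratios, file.path(out_dir, "ratios.csv"))
    data.table::fwrite(processed$qc, file.path(out_dir, "qc.csv"))
    write_stats_report(report, out_dir)
    tryCatch({
      p <- plot_ratio_boxplot(processed$ratios)
      grDevices::png(file.path(out_dir, "boxplot.png"), width = 900, height = 500)
      print(p)
      grDevices::dev.off()
    }, error = function(e) {
      warning(sprintf("could not render boxplot: %s", conditionMessage(e)),
              call. = FALSE)
    })
    yaml::write_yaml(list(config = unclass(config), seed = config$seed,
                          package_version = as.character(utils::packageVersion("vibremg")),
                          r_version = R.version.string),
                     file.path(out_dir, "provenance.yml"))
  }
  list(ratios = processed$ratios, qc = processed$qc, report = report)
}
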