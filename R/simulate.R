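#' Synthetic-study configuration
#'
#' Parameters of the synthetic two-session crossover generator. The defaults
#' encode the study protocol the analysis targets: 30 participants, 60-s
#' trials sampled at 1024 Hz, 60-bpm elbow flexion-extension, and a
#' follow-up effect profile in which post-vibration antagonist activation is
#' multiplicatively attenuated for about 20 minutes before returning toward
#' baseline, while the control session stays at 1.
#'
#' @param n_participants number of participants (each does both sessions).
#' @param fs_hz raw sampling rate in Hz.
#' @param trial_s movement duration per trial, seconds (excludes lead-in).
#' @param cadence_bpm movement cadence; one beat = one flexion-extension cycle.
#' @param rom_amplitude_deg half-range of the joint angle (peak-to-peak is
#'   twice this).
#' @param angle_noise_sd_deg SD of the smoothed angle noise, degrees.
#' @param burst_amplitude_uv mean envelope amplitude of the extensor burst, µV.
#' @param burst_duty fraction of each cycle occupied by the extension burst.
#' @param noise_sd_uv SD of the additive baseline instrumentation noise, µV.
#' @param subject_sd_log between-subject SD of log burst amplitude.
#' @param trial_jitter_log within-subject trial-to-trial SD of log amplitude.
#' @param effect_profile named list with elements `control` and `fmv`, each a
#'   vector of true multiplicative ratios named by follow-up minutes
#'   ("0", "5", ..., "30").
#' @param lead_in_s quiescent pre-movement segment, seconds.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 30, fs_hz = 1024, trial_s = 60,
                       cadence_bpm = 60, rom_amplitude_deg = 45,
                       angle_noise_sd_deg = 0.5, burst_amplitude_uv = 80,
                       burst_duty = 0.4, noise_sd_uv = 8,
                       subject_sd_log = 0.3, trial_jitter_log = 0.1,
                       effect_profile = NULL, lead_in_s = 3, seed = 20260101) {
  fups <- as.character(trial_schedule[setdiff(names(trial_schedule), "pre")])
  if (is.null(effect_profile)) {
    effect_profile <- list(
      control = stats::setNames(rep(1, 7), fups),
      fmv = stats::setNames(c(0.84, 0.80, 0.86, 0.84, 0.85, 0.97, 0.93), fups))
  }
  for (s in sessions) {
    if (!all(fups %in% names(effect_profile[[s]]))) {
      parameter_error(sprintf("effect_profile$%s must cover follow-ups %s",
                              s, paste(fups, collapse = ", ")))
    }
    if (any(effect_profile[[s]] <= 0)) parameter_error("true ratios must be > 0")
  }
  if (burst_amplitude_uv < 0 || noise_sd_uv < 0) {
    parameter_error("amplitudes must be non-negative")
  }
  if (burst_duty <= 0 || burst_duty >= 1) parameter_error("burst_duty must be in (0, 1)")
  structure(
    list(n_participants = n_participants, fs_hz = fs_hz, trial_s = trial_s,
         cadence_bpm = cadence_bpm, rom_amplitude_deg = rom_amplitude_deg,
         angle_noise_sd_deg = angle_noise_sd_deg,
         burst_amplitude_uv = burst_amplitude_uv, burst_duty = burst_duty,
         noise_sd_uv = noise_sd_uv, subject_sd_log = subject_sd_log,
         trial_jitter_log = trial_jitter_log, effect_profile = effect_profile,
         lead_in_s = lead_in_s, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a joint-angle (ROM) trace
#'
#' A quiescent lead-in at the resting angle followed by sinusoidal
#' flexion-extension at the configured cadence: angle
#' `A * (1 - cos(2 pi f t))` spans 0 to `2 * rom_amplitude_deg` degrees, with
#' peak flexion mid-cycle. Smoothed Gaussian angle noise is added throughout.
#' Consumes the current RNG stream.
#'
#' @param cfg a `sim_config`.
#' @return Numeric vector of `(lead_in_s + trial_s) * fs_hz` angle samples.
#' @export
simulate_rom <- function(cfg) {
  n_lead <- round(cfg$lead_in_s * cfg$fs_hz)
  n_move <- round(cfg$trial_s * cfg$fs_hz)
  f <- cfg$cadence_bpm / 60
  t_move <- (seq_len(n_move) - 1) / cfg$fs_hz
  rom <- c(rep(0, n_lead), cfg$rom_amplitude_deg * (1 - cos(2 * pi * f * t_move)))
  if (cfg$angle_noise_sd_deg > 0) {
    # slow drift-like noise (IMU angle estimates wander smoothly): two
    # cascaded 1-s moving averages keep the noise speed well under the
    # movement-onset criterion
    w <- round(cfg$fs_hz)
    noise <- moving_average(moving_average(stats::rnorm(length(rom)), w), w)
    noise <- noise / stats::sd(noise) * cfg$angle_noise_sd_deg
    rom <- rom + noise
  }
  rom
}

# Band-limited unit-RMS Gaussian noise: white noise shaped by the same
# zero-phase Butterworth band-pass the pipeline uses, so the filtering stage
# is non-trivial on synthetic data.
bandlimited_noise <- function(n, fs_hz, low_hz = 20, high_hz = 450) {
  x <- bandpass_filter(stats::rnorm(n), fs_hz, low_hz, high_hz)
  x / sqrt(mean(x^2))
}

#' Simulate a triceps sEMG trace for a given ROM trace
#'
#' Band-limited (20-450 Hz) Gaussian carrier noise is amplitude-modulated by
#' a per-cycle burst envelope gated to the extension phase of each
#' flexion-extension cycle (the triceps is the elbow extensor): a raised-
#' cosine burst of width `burst_duty` of the cycle, centred mid-extension
#' and normalized so its mean height over the burst is 1. The burst gain is
#' `burst_amplitude_uv * exp(subject_effect) * exp(trial jitter) *
#' trial_ratio`. White instrumentation noise of SD `noise_sd_uv` is added
#' throughout, including the lead-in; no bursts occur during the lead-in.
#' Consumes the current RNG stream.
#'
#' @param rom ROM trace from [simulate_rom()] under the same `cfg`.
#' @param cfg a `sim_config`.
#' @param subject_effect participant's log-amplitude offset.
#' @param trial_ratio true multiplicative ratio for this trial (1 at baseline).
#' @return Numeric vector of sEMG samples in µV, same length as `rom`.
#' @export
simulate_emg <- function(rom, cfg, subject_effect = 0, trial_ratio = 1) {
  n <- length(rom)
  n_lead <- round(cfg$lead_in_s * cfg$fs_hz)
  f <- cfg$cadence_bpm / 60
  t <- (seq_len(n) - 1) / cfg$fs_hz
  # cycle phase in [0, 1): 0 at movement start (full extension), 0.5 at peak
  # flexion; extension phase is (0.5, 1), burst centred at 0.75
  phase <- (t - cfg$lead_in_s) * f
  phase <- phase - floor(phase)
  u <- (phase - 0.75) / cfg$burst_duty + 0.5      # position within the burst
  gate <- numeric(n)
  in_burst <- u >= 0 & u < 1
  gate[in_burst] <- 1 - cos(2 * pi * u[in_burst])  # mean 1 over the burst
  gate[seq_len(min(n_lead, n))] <- 0
  gain <- cfg$burst_amplitude_uv * exp(subject_effect) *
    exp(stats::rnorm(1, 0, cfg$trial_jitter_log)) * trial_ratio
  carrier <- bandlimited_noise(n, cfg$fs_hz)
  gain * gate * carrier + stats::rnorm(n, 0, cfg$noise_sd_uv)
}

# One trial as an emg_recording (consumes the RNG stream).
simulate_trial <- function(cfg, participant_id, session, trial_label,
                           subject_effect, trial_ratio) {
  rom <- simulate_rom(cfg)
  emg <- simulate_emg(rom, cfg, subject_effect, trial_ratio)
  recording(emg = emg, rom = rom, fs_hz = cfg$fs_hz,
            participant_id = participant_id, session = session,
            trial_label = trial_label,
            expected_duration_s = cfg$trial_s + cfg$lead_in_s)
}

#' Simulate a complete crossover study
#'
#' Generates every trial of an `n_participants` x 2-session x 8-trial
#' crossover: per participant-session one baseline (`pre`, true ratio 1) and
#' seven follow-up trials whose true ratios come from
#' `cfg$effect_profile[[session]]`. Each participant's log-amplitude offset
#' is drawn once and shared across both sessions (within-subject crossover).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @param out_dir if `NULL` (default) the study is returned in memory; else
#'   trials are written as CSV files plus per-session `manifest.yml` under
#'   `out_dir/<participant>/<session>/`, the layout read by [load_study()].
#' @return An `emg_study` (list of `session_manifest`); with `out_dir`, the
#'   manifests reference the files on disk.
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  labels <- names(trial_schedule)
  with_seed(cfg$seed, {
    subject_effects <- stats::rnorm(cfg$n_participants, 0, cfg$subject_sd_log)
    ids <- sprintf("P%02d", seq_len(cfg$n_participants))
    manifests <- list()
    for (i in seq_len(cfg$n_participants)) {
      for (s in sessions) {
        profile <- cfg$effect_profile[[s]]
        trials <- list()
        for (lab in labels) {
          ratio <- if (lab == "pre") 1 else unname(profile[as.character(trial_schedule[lab])])
          rec <- simulate_trial(cfg, ids[i], s, lab, subject_effects[i], ratio)
          if (is.null(out_dir)) {
            trials[[lab]] <- rec
          } else {
            sess_dir <- file.path(out_dir, ids[i], s)
            write_trial(rec, file.path(sess_dir, paste0(lab, ".csv")))
            trials[[lab]] <- paste0(lab, ".csv")
          }
        }
        if (!is.null(out_dir)) {
          yaml::write_yaml(
            list(participant_id = ids[i], session = s, trials = trials),
            file.path(out_dir, ids[i], s, "manifest.yml"))
          trials <- lapply(trials, function(rel) file.path(out_dir, ids[i], s, rel))
        }
        manifests[[length(manifests) + 1L]] <-
          session_manifest(ids[i], s, trials)
      }
    }
    structure(manifests, class = "emg_study")
  })
}

#' Simulate a ratio table directly (no raw signals)
#'
#' Draws post/pre ratios from the generative model the statistical stage
#' assumes: `log(ratio) = log(true ratio) + b_i + e_ij` with a per-
#' participant responsiveness intercept `b_i ~ N(0, subject_sd^2)` shared
#' across both sessions and trial-level noise `e_ij ~ N(0, resid_sd^2)`.
#' The defaults give total ratio SDs near 0.3, matching what sEMG ratio
#' studies of this design typically report. Useful for Monte-Carlo studies
#' of the statistical families where raw-signal synthesis would dominate
#' the run time.
#'
#' @param n_participants number of participants.
#' @param effect_profile as in [sim_config()]; defaults to the [sim_config()]
#'   default.
#' @param subject_sd between-subject SD of the log-ratio intercept.
#' @param resid_sd trial-level log-ratio SD.
#' @param seed integer seed.
#' @return A `ratio_table` (with `pre_rms_uv`/`post_rms_uv` set so the ratio
#'   column is consistent).
#' @export
simulate_ratio_table <- function(n_participants = 30, effect_profile = NULL,
                                 subject_sd = 0.3, resid_sd = 0.15,
                                 seed = 20260101) {
  if (is.null(effect_profile)) effect_profile <- sim_config()$effect_profile
  fups <- sort(as.integer(names(effect_profile$control)))
  ids <- sprintf("P%02d", seq_len(n_participants))
  with_seed(seed, {
    b <- stats::rnorm(n_participants, 0, subject_sd)
    rows <- list()
    for (i in seq_len(n_participants)) {
      for (s in sessions) {
        r_true <- effect_profile[[s]][as.character(fups)]
        lr <- log(r_true) + b[i] + stats::rnorm(length(fups), 0, resid_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[i], session = s, follow_up_min = fups,
          pre_rms_uv = 1, post_rms_uv = exp(lr), ratio = exp(lr),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("ratio_table", "data.frame")
    out
  })
}
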