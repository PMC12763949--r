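# Shared fixtures, all generated in code.

# A short protocol-like ROM: flat lead-in then 1-cos flexion-extension.
make_rom <- function(lead_s = 2, move_s = 20, fs = 1024, cadence_bpm = 60,
                     amplitude = 45) {
  f <- cadence_bpm / 60
  t <- seq_len(move_s * fs) / fs
  c(rep(0, lead_s * fs), amplitude * (1 - cos(2 * pi * f * t)))
}

# A quick synthetic recording (short trials keep unit tests fast).
make_recording <- function(seed = 42, trial_s = 20, lead_in_s = 2,
                           trial_ratio = 1, subject_effect = 0,
                           cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- sim_config(n_participants = 1, trial_s = trial_s,
                      lead_in_s = lead_in_s, seed = seed)
  }
  vibremg:::with_seed(seed, {
    rom <- simulate_rom(cfg)
    emg <- simulate_emg(rom, cfg, subject_effect, trial_ratio)
    recording(emg, rom, cfg$fs_hz,
              expected_duration_s = cfg$trial_s + cfg$lead_in_s)
  })
}

# Brute-force step-up oracle for the Benjamini-Hochberg adjustment:
# adjusted_i = min over j with p_(j) >= p_i of m * p_(j) / rank_j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  s <- sort(p)
  vapply(p, function(pi) {
    js <- which(s >= pi)
    min(1, min(m * s[js] / js))
  }, numeric(1))
}

# Brute-force total RMS over the selected span of a corrected envelope.
rms_bruteforce <- function(cenv, cs) {
  span <- vibremg:::selected_span(cs)
  vals <- c()
  for (k in seq_along(cenv$values)) {
    t_k <- (k - 1) / cenv$fs_env_hz
    if (t_k >= span[1] && t_k < span[2]) vals <- c(vals, cenv$values[k])
  }
  sqrt(mean(vals^2))
}

# Ratio table with exactly normal ratios (for paired-test contract checks).
make_normal_ratio_table <- function(n = 30, shift_fmv = 0, sd = 0.1, seed = 42) {
  vibremg:::with_seed(seed, {
    fups <- c(0L, 5L, 10L, 15L, 20L, 25L, 30L)
    rows <- list()
    for (i in seq_len(n)) {
      for (s in c("control", "fmv")) {
        r <- 1 + (s == "fmv") * shift_fmv + rnorm(length(fups), 0, sd)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("P%02d", i), session = s,
          follow_up_min = fups, pre_rms_uv = 1, post_rms_uv = r, ratio = r)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("ratio_table", "data.frame")
    out
  })
}
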