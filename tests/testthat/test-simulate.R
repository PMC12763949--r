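test_that("simulated angle traces carry the configured cadence and lead-in", {
  cfg <- sim_config(n_participants = 1, seed = 42)
  set.seed(1)
  rom <- simulate_rom(cfg)
  expect_length(rom, (60 + 3) * 1024)
  cs <- detect_cycles(rom, cfg$fs_hz)
  expect_true(nrow(cs$cycles) %in% 58:60)
  onset <- detect_movement_onset(rom, cfg$fs_hz)
  expect_equal(onset, cfg$lead_in_s, tolerance = 0.25)

  # halving the cadence doubles the cycle duration
  cfg30 <- sim_config(n_participants = 1, cadence_bpm = 30, seed = 42)
  set.seed(1)
  rom30 <- simulate_rom(cfg30)
  cs30 <- detect_cycles(rom30, cfg30$fs_hz, cadence_bpm = 30)
  expect_equal(median(cs30$cycles$end_s - cs30$cycles$start_s), 2.0,
               tolerance = 0.05)

  # a zero-amplitude "movement" cannot be segmented
  cfg0 <- sim_config(n_participants = 1, rom_amplitude_deg = 0, seed = 42)
  set.seed(1)
  rom0 <- simulate_rom(cfg0)
  expect_error(detect_cycles(rom0, cfg0$fs_hz),
               class = "vibremg_segmentation_error")
})

test_that("simulated EMG is burst-gated to the extension phase", {
  cfg <- sim_config(n_participants = 1, trial_s = 20, lead_in_s = 2, seed = 42)
  set.seed(2)
  rom <- simulate_rom(cfg)
  emg <- simulate_emg(rom, cfg, subject_effect = 0, trial_ratio = 1)
  expect_length(emg, length(rom))
  # lead-in contains noise only: its RMS is near the configured noise SD
  lead <- emg[seq_len(2 * 1024)]
  expect_equal(sqrt(mean(lead^2)), cfg$noise_sd_uv, tolerance = 0.1)
  # movement segment carries far more energy than the lead-in
  move <- emg[-seq_len(2 * 1024)]
  expect_gt(sqrt(mean(move^2)), 3 * sqrt(mean(lead^2)))
})

test_that("a burst-free trial retains almost no energy after thresholding", {
  cfg <- sim_config(n_participants = 1, trial_s = 20, lead_in_s = 2,
                    burst_amplitude_uv = 0, seed = 42)
  rates <- vapply(1:5, function(i) {
    set.seed(100 + i)
    rom <- simulate_rom(cfg)
    emg <- simulate_emg(rom, cfg, 0, 1)
    rec <- recording(emg, rom, cfg$fs_hz, expected_duration_s = 22)
    pr <- process_recording(rec, pipeline_config())
    pr$rms
  }, numeric(1))
  # compare with an active trial at default burst amplitude
  set.seed(100)
  cfg_on <- sim_config(n_participants = 1, trial_s = 20, lead_in_s = 2,
                       seed = 42)
  rom <- simulate_rom(cfg_on)
  emg <- simulate_emg(rom, cfg_on, 0, 1)
  active_rms <- process_recording(
    recording(emg, rom, cfg_on$fs_hz, expected_duration_s = 22))$rms
  expect_lt(mean(rates), 0.05 * active_rms)
})

test_that("doubling the burst amplitude doubles RMS but leaves ratios alone", {
  cfg1 <- sim_config(n_participants = 1, trial_s = 20, lead_in_s = 2, seed = 1)
  cfg2 <- sim_config(n_participants = 1, trial_s = 20, lead_in_s = 2,
                     burst_amplitude_uv = 160, seed = 1)
  study1 <- simulate_study(cfg1)
  study2 <- simulate_study(cfg2)
  rt1 <- run_process(study1)$ratios
  rt2 <- run_process(study2)$ratios
  expect_equal(rt2$ratio, rt1$ratio, tolerance = 0.05)
  expect_gt(median(rt2$post_rms_uv / rt1$post_rms_uv), 1.7)
})

test_that("study generation is deterministic and honours the crossover design", {
  cfg <- sim_config(n_participants = 2, trial_s = 12, lead_in_s = 2, seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_length(s1, 4L)
  expect_identical(
    vapply(s1, function(m) m$session, ""),
    rep(c("control", "fmv"), 2))
  expect_identical(s1[[1]]$trials$pre$emg, s2[[1]]$trials$pre$emg)
  expect_identical(s1[[4]]$trials$post30$rom, s2[[4]]$trials$post30$rom)

  # on disk: same seed gives byte-identical trees
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  expect_length(f1, 4L * 9L)   # 8 trials + manifest per session
  sum1 <- tools::md5sum(file.path(d1, f1))
  sum2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(sum1), unname(sum2))
})

test_that("ratio-level simulation matches its generative model", {
  rt <- simulate_ratio_table(n_participants = 200, seed = 99)
  expect_identical(nrow(rt), 200L * 2L * 7L)
  agg <- aggregate(ratio ~ session + follow_up_min, rt, function(x) mean(log(x)))
  truth <- sim_config()$effect_profile
  fmv <- agg[agg$session == "fmv", ]
  expect_lt(max(abs(fmv$ratio[order(fmv$follow_up_min)] -
                      unname(log(truth$fmv)))), 0.07)
  ctrl <- agg[agg$session == "control", ]
  expect_lt(max(abs(ctrl$ratio)), 0.07)
  # same seed reproduces every number exactly
  expect_identical(rt$ratio, simulate_ratio_table(200, seed = 99)$ratio)
})

test_that("simulation configs validate their inputs", {
  expect_error(sim_config(burst_duty = 1.2), class = "vibremg_parameter_error")
  expect_error(sim_config(effect_profile = list(
    control = c("0" = 1), fmv = c("0" = 0.8))),
    class = "vibremg_parameter_error")
  bad <- sim_config()$effect_profile
  bad$fmv["5"] <- -1
  expect_error(sim_config(effect_profile = bad),
               class = "vibremg_parameter_error")
})
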