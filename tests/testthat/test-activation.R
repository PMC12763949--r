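test_that("movement onset is located from the angle speed criterion", {
  fs <- 1024
  # flat for 2 s then 60-bpm sinusoid of +/-45 degrees: onset known to be 2 s
  rom <- c(rep(0, 2 * fs), 45 * sin(2 * pi * seq_len(20 * fs) / fs))
  onset <- detect_movement_onset(rom, fs)
  expect_equal(onset, 2.0, tolerance = 0.25)  # within one envelope sample

  # movement from the very first sample: onset 0 with a warning
  rom0 <- 45 * sin(2 * pi * seq_len(20 * fs) / fs + pi / 4)
  expect_warning(onset0 <- detect_movement_onset(rom0, fs), "lead-in")
  expect_identical(onset0, 0)

  # sub-threshold noise only: no movement
  set.seed(1)
  expect_error(detect_movement_onset(rep(0, 20 * fs), fs),
               class = "vibremg_onset_error")
  slow <- cumsum(rnorm(20 * fs, 0, 0.001))
  expect_error(detect_movement_onset(slow, fs), class = "vibremg_onset_error")
})

test_that("threshold window centres on the pre-onset minimum and clips", {
  # envelope with a known pre-onset minimum at index 10 (0-based)
  vals <- c(rep(2, 10), 0.5, rep(2, 189))
  env <- structure(list(values = vals, fs_env_hz = 4, window_s = 0.25,
                        source_fs_hz = 1024), class = "emg_envelope")
  thr <- estimate_threshold(env, onset_s = 25)  # onset at envelope index 100
  expect_identical(thr$min_index, 10L)
  expect_equal(thr$window_bounds, c(0, 40))    # 10 - 30 clips to 0; 10 + 30
  win <- vals[1:40]
  expect_equal(thr$noise_mean, mean(win))
  expect_equal(thr$noise_sd, sqrt(mean((win - mean(win))^2)))
  expect_equal(thr$threshold, thr$noise_mean + 3 * thr$noise_sd)

  # constant pre-onset segment: SD 0, threshold equals the constant
  env_c <- structure(list(values = c(rep(1, 50), rep(5, 50)), fs_env_hz = 4,
                          window_s = 0.25, source_fs_hz = 1024),
                     class = "emg_envelope")
  thr_c <- estimate_threshold(env_c, onset_s = 12.5)
  expect_equal(thr_c$threshold, 1.0)

  # no pre-onset segment
  expect_error(estimate_threshold(env, onset_s = 0),
               class = "vibremg_threshold_error")
})

test_that("threshold approximates mean + 3 SD of the realized noise window", {
  set.seed(42)
  noise <- rnorm(60, mean = 2, sd = 0.5)
  env <- structure(list(values = c(noise, rep(50, 200)), fs_env_hz = 4,
                        window_s = 0.25, source_fs_hz = 1024),
                   class = "emg_envelope")
  thr <- estimate_threshold(env, onset_s = 15)
  # oracle: direct mean + 3 SD over the realized window values
  win <- env$values[(thr$window_bounds[1] + 1):thr$window_bounds[2]]
  expect_equal(thr$threshold, mean(win) + 3 * sqrt(mean((win - mean(win))^2)))
  expect_equal(thr$threshold, 3.5, tolerance = 0.2)
})

test_that("threshold subtraction keeps only suprathreshold activity", {
  env <- structure(list(values = c(1, 4, 2), fs_env_hz = 4, window_s = 0.25,
                        source_fs_hz = 1024), class = "emg_envelope")
  ce <- apply_threshold(env, 2)
  expect_equal(ce$values, c(0, 2, 0))
  expect_identical(ce$active_mask, c(FALSE, TRUE, FALSE))

  # zero threshold is the identity on positive envelopes
  ce0 <- apply_threshold(env, 0)
  expect_equal(ce0$values, env$values)
  expect_true(all(ce0$active_mask))
  expect_error(apply_threshold(env, -1), class = "vibremg_parameter_error")
})

test_that("thresholding is monotone and translation invariant", {
  set.seed(7)
  vals <- abs(rnorm(240, 5, 2))
  env <- structure(list(values = vals, fs_env_hz = 4, window_s = 0.25,
                        source_fs_hz = 1024), class = "emg_envelope")
  lo <- apply_threshold(env, 2)$values
  hi <- apply_threshold(env, 4)$values
  expect_true(all(hi <= lo))

  # adding c shifts the threshold by exactly c, corrected output unchanged
  onset_s <- 10
  thr1 <- estimate_threshold(env, onset_s)
  env2 <- env
  env2$values <- env$values + 3
  thr2 <- estimate_threshold(env2, onset_s)
  expect_equal(thr2$threshold, thr1$threshold + 3)
  expect_equal(apply_threshold(env2, thr2)$values,
               apply_threshold(env, thr1)$values)
})

test_that("pure noise is almost entirely suppressed by the mean + 3 SD rule", {
  # noise-only trial: suprathreshold fraction should be small, and the
  # retained energy near zero relative to an active signal
  set.seed(42)
  frac <- replicate(30, {
    vals <- abs(rnorm(240, 8, 0.5))
    env <- structure(list(values = vals, fs_env_hz = 4, window_s = 0.25,
                          source_fs_hz = 1024), class = "emg_envelope")
    thr <- estimate_threshold(env, onset_s = 15)
    mean(apply_threshold(env, thr)$active_mask)
  })
  expect_lt(mean(frac), 0.02)
})
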