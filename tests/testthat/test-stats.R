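test_that("BH adjustment matches the brute-force step-up oracle exactly", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)       # single p unchanged
  expect_equal(benjamini_hochberg(rep(0.03, 5)), rep(0.03 * 5 / 5, 5))

  set.seed(42)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)                        # ties occur often
    adj <- benjamini_hochberg(p)
    expect_identical(adj, bh_oracle(p))
    # independent cross-check (different evaluation order, so tiny float slack)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "vibremg_parameter_error")
})

test_that("BH adjustment preserves the ordering of raw p-values", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(2:15, 1))
    adj <- benjamini_hochberg(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("the intragroup model recovers injected attenuation", {
  profile <- sim_config()$effect_profile
  # averaged over replicates, exp(coefficient) is within 0.05 of the truth
  est <- matrix(0, nrow = 20, ncol = 7)
  sig <- matrix(FALSE, nrow = 20, ncol = 7)
  for (r in 1:20) {
    rt <- simulate_ratio_table(n_participants = 30, seed = 5000 + r)
    fit <- fit_intragroup(rt, "fmv")
    est[r, ] <- fit$ratio_estimate
    sig[r, ] <- fit$p_adj < 0.05
  }
  truth <- unname(profile$fmv)
  expect_lt(max(abs(colMeans(est) - truth)), 0.05)
  # attenuated points (true ratio <= 0.86) are detected in the majority of
  # replicates
  expect_true(all(colMeans(sig)[truth <= 0.86] > 0.5))
})

test_that("the intragroup model handles degenerate and invalid input", {
  rt <- make_normal_ratio_table(n = 10, sd = 0)  # all ratios exactly 1
  expect_warning(fit <- fit_intragroup(rt, "control"), "degenerate")
  expect_true(all(fit$p_raw == 1))
  expect_true(all(fit$estimate == 0))

  rt2 <- simulate_ratio_table(n_participants = 5, seed = 1)
  rt2$ratio[1] <- -0.1
  expect_error(fit_intragroup(rt2, "control"), class = "vibremg_data_error")
  rt3 <- simulate_ratio_table(n_participants = 5, seed = 1)
  expect_error(fit_intragroup(rt3[rt3$participant_id == "P01", ], "control"),
               class = "vibremg_fit_error")
})

test_that("log-scale and raw-scale intragroup variants agree on direction", {
  rt <- simulate_ratio_table(n_participants = 30, seed = 77)
  log_fit <- fit_intragroup(rt, "fmv", scale = "log")
  raw_fit <- fit_intragroup(rt, "fmv", scale = "raw")
  clear <- abs(log_fit$estimate) > 0.05   # away from the null the sign agrees
  expect_equal(sign(log_fit$estimate)[clear], sign(raw_fit$estimate)[clear])
  expect_equal(log_fit$mean_ratio, raw_fit$mean_ratio)
})

test_that("satterthwaite tests are available and never more liberal at the null", {
  skip_if_not_installed("lmerTest")
  rt <- simulate_ratio_table(n_participants = 12, seed = 3)
  wald <- fit_intragroup(rt, "control", df_method = "wald")
  satt <- fit_intragroup(rt, "control", df_method = "satterthwaite")
  expect_true(all(satt$p_raw >= wald$p_raw - 1e-10))
})

test_that("paired comparisons gate on normality and report df = n - 1", {
  rt <- make_normal_ratio_table(n = 30, shift_fmv = -0.15, seed = 42)
  res <- compare_groups(rt)
  expect_identical(nrow(res), 7L)
  expect_true(all(res$test_used == "paired_t"))
  expect_true(all(res$df == 29))
  expect_true(all(res$n_pairs == 30))
  expect_true(all(res$mean_diff < 0))

  # heavy-tailed differences push the gate to the signed-rank test
  set.seed(42)
  rt2 <- make_normal_ratio_table(n = 30, seed = 1)
  spike <- rt2$session == "fmv" & rt2$participant_id %in% sprintf("P%02d", 1:4)
  rt2$ratio[spike] <- rt2$ratio[spike] + 8   # gross outliers
  res2 <- compare_groups(rt2)
  expect_true(any(res2$test_used == "wilcoxon"))
  expect_true(all(is.na(res2$df[res2$test_used == "wilcoxon"])))
})

test_that("paired comparisons handle degenerate and undersized input", {
  rt <- make_normal_ratio_table(n = 5, sd = 0)   # fmv == control everywhere
  w <- capture_warnings(res <- compare_groups(rt))
  expect_true(any(grepl("zero", w)))
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$test_used == "degenerate"))

  rt2 <- make_normal_ratio_table(n = 2)
  expect_error(compare_groups(rt2), class = "vibremg_test_error")
})

test_that("the stats report bundles summaries, contrasts and paired tests", {
  rt <- simulate_ratio_table(n_participants = 20, seed = 8)
  rep <- stats_report(rt)
  expect_named(rep$intragroup, c("control", "fmv"))
  expect_identical(nrow(rep$summary), 14L)      # 2 sessions x 7 points
  expect_identical(nrow(rep$intergroup), 7L)
  expect_true(all(c("mean", "sd", "q1", "median", "q3") %in%
                    names(rep$summary)))
  expect_output(print(rep), "adj. p")

  dir <- withr::local_tempdir()
  write_stats_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "summary.csv", "intragroup_control.csv", "intragroup_fmv.csv",
    "intergroup.csv")))))

  p <- plot_ratio_boxplot(rt)
  expect_s3_class(p, "ggplot")
})
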