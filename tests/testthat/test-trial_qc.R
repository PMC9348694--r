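test_that("pre-stimulus variation rule flags by the configured statistic", {
  times <- tf_time_grid()
  n_pre <- sum(times < 0)

  # constant pre-stimulus trace: never flagged under either statistic
  tc <- matrix(1, 4, length(times))
  h <- make_hfb(tc, times)
  expect_false(any(flag_prestim_variation(h, qc_config())))
  expect_false(any(flag_prestim_variation(
    h, qc_config(prestim_stat = "range"))))

  # step from 1.0 to 1.6 pre-onset: range 0.6 exceeds the 0.5 threshold
  tc2 <- matrix(1, 3, length(times))
  pre <- which(times >= -0.2 & times < 0)
  tc2[2, pre[11:length(pre)]] <- 1.6
  h2 <- make_hfb(tc2, times)
  flags_range <- flag_prestim_variation(h2, qc_config(prestim_stat = "range"))
  expect_identical(flags_range, c(FALSE, TRUE, FALSE))
  # the same step has SD 0.3 and survives the SD reading
  expect_false(any(flag_prestim_variation(h2, qc_config())))

  # baseline-corrected input is rejected (state flag honoured)
  hbc <- make_hfb(tc, times, baseline_corrected = TRUE)
  expect_error(flag_prestim_variation(hbc), "baseline-corrected")
})

test_that("baseline-outlier rule flags 3-sigma deviants in a single pass", {
  times <- tf_time_grid()
  # all equal baselines: sd = 0, strict inequality, nothing flagged
  h0 <- make_hfb(matrix(1, 5, length(times)), times)
  expect_false(any(flag_baseline_outlier(h0, qc_config())))

  # 100 trials at 0, one at 10: only that trial exceeds 3 sd computed
  # with the outlier included
  tc <- matrix(0, 101, length(times))
  tc[101, ] <- 10
  h1 <- make_hfb(tc, times)
  m <- c(rep(0, 100), 10)
  expect_gt(abs(10 - mean(m)), 3 * sqrt(mean((m - mean(m))^2)))
  flags <- flag_baseline_outlier(h1, qc_config())
  expect_identical(which(flags), 101L)

  # Monte-Carlo two-sided 3-sigma tail on a Gaussian null: ~0.27%
  set.seed(2)
  n <- 10000
  tc_null <- matrix(rnorm(n), n, length(times))
  h_null <- make_hfb(tc_null, times)
  rate <- mean(flag_baseline_outlier(h_null, qc_config()))
  expect_equal(rate, 0.0027, tolerance = 0.5)

  expect_error(flag_baseline_outlier(
    make_hfb(matrix(1, 2, length(times)), times)), "at least 3")
})

test_that("QC flags clear keep flags monotonically without touching data", {
  times <- tf_time_grid()
  set.seed(9)
  tc <- matrix(rnorm(10 * length(times)) + 1, 10)
  h <- make_hfb(tc, times)
  fa <- c(rep(FALSE, 8), TRUE, FALSE)
  fb <- c(TRUE, rep(FALSE, 9))

  out <- apply_qc(h, fa, fb)
  expect_identical(out$timecourse, h$timecourse)   # values untouched
  expect_identical(which(!out$trials$keep), c(1L, 9L))  # union of rules
  expect_equal(attr(out, "qc_counts"), c(1L, 1L))

  # idempotent re-application
  out2 <- apply_qc(out, fa, fb)
  expect_identical(out2$trials$keep, out$trials$keep)

  # no flags is the identity
  expect_identical(apply_qc(h, rep(FALSE, 10))$trials$keep, h$trials$keep)

  expect_error(apply_qc(h, rep(TRUE, 10)), "every trial")
})

test_that("exclusion is monotone in the thresholds", {
  times <- tf_time_grid()
  set.seed(10)
  tc <- matrix(rnorm(200 * length(times), sd = 0.3) + 1, 200)
  h <- make_hfb(tc, times)
  for (stat in c("sd", "range")) {
    f_loose <- flag_prestim_variation(
      h, qc_config(prestim_range_threshold = 0.6, prestim_stat = stat))
    f_tight <- flag_prestim_variation(
      h, qc_config(prestim_range_threshold = 0.3, prestim_stat = stat))
    expect_true(all(f_tight[f_loose]))   # lowering never unflags
  }
  b_loose <- flag_baseline_outlier(h, qc_config(baseline_sd_threshold = 3))
  b_tight <- flag_baseline_outlier(h, qc_config(baseline_sd_threshold = 2))
  expect_true(all(b_tight[b_loose]))
})

test_that("injected artifact trials are all caught by QC at default thresholds", {
  plan <- build_sequential_plan(stim_params())
  plan <- mark_oddballs(plan, seed = 1)
  plan$events <- retained_trial_filter(plan$events, "sequential")
  sc <- synth_config(channels = data.frame(
    name = c("s1", "s2", "s3"), archetype = "silent",
    n_pref = NA_integer_))
  sim <- simulate_run(plan, sc, seed = 55)
  art <- inject_artifact_trials(sim$recording, sim$events,
                                fraction = 0.1, seed = 56)
  ep <- preprocess_run(art$recording, sim$events, default_config(),
                       "sequential")
  tf <- normalize_power(timefreq_power(ep, 1, freqs = seq(60, 120, 2)))
  h <- extract_hfb(tf)
  flagged <- flag_prestim_variation(h) | flag_baseline_outlier(h)
  expect_true(all(flagged[art$artifact]))
})
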