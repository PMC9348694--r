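test_that("evoked removal zeroes the per-condition mean and removes injected waveforms", {
  fs <- 512
  set.seed(21)
  n_t <- 512
  data <- array(rnorm(12 * 1 * n_t), c(12, 1, n_t))
  cond <- rep(c("1", "4"), each = 6)
  # inject a strong common waveform into condition "4"
  wave <- 10 * sin(2 * pi * 7 * (1:n_t) / fs)
  for (i in 7:12) data[i, 1, ] <- data[i, 1, ] + wave
  ep <- make_epochs(data, fs, trial_type = cond)

  var_before <- var(apply(ep$data[7:12, 1, ], 1, mean))
  out <- remove_evoked(ep)
  for (cc in c("1", "4")) {
    m <- colMeans(out$data[cond == cc, 1, ])
    expect_equal(max(abs(m)), 0, tolerance = 1e-12)
  }

  # identical trials collapse to exactly zero
  same <- array(rep(rnorm(n_t), each = 4), c(4, 1, n_t))
  ep_same <- make_epochs(same, fs, trial_type = rep("2", 4))
  out_same <- remove_evoked(ep_same)
  expect_equal(max(abs(out_same$data)), 0)

  # cross-trial variance at evoked latencies returns to background level
  ep_one <- make_epochs(data[7:12, , , drop = FALSE], fs,
                        trial_type = rep("4", 6))
  cleaned <- remove_evoked(ep_one)
  v <- apply(cleaned$data[, 1, ], 2, var)
  expect_lt(mean(v), 1.5)   # background variance is 1

  few <- make_epochs(data[1:3, , , drop = FALSE], fs,
                     trial_type = c("1", "1", "2"))
  expect_error(remove_evoked(few), "at least 2")
})

test_that("tapered sliding-window power matches the naive direct-sum DFT oracle", {
  fs <- 512
  set.seed(31)
  # 5 trials x 2 channels x 0.5 s epochs, random content
  data <- array(rnorm(5 * 2 * 256), c(5, 2, 256))
  ep <- make_epochs(data, fs, t0 = -0.25)
  freqs <- c(8, 24, 60, 110)
  times <- c(-0.05, 0, 0.1)
  for (ch in 1:2) {
    got <- timefreq_power(ep, ch, window_s = 0.2, freqs = freqs,
                          times = times)
    want <- naive_tf_power(ep, ch, window_s = 0.2, freqs = freqs,
                           times = times)
    expect_equal(got$power, want, tolerance = 1e-9)
  }
})

test_that("power of a stationary sinusoid is flat over time and peaks at its frequency", {
  fs <- 2048
  n_t <- 3073
  t <- seq(-0.5, 1.0, length.out = n_t)
  x <- sin(2 * pi * 80 * t)
  data <- array(rep(x, each = 2), c(2, 1, n_t))
  ep <- make_epochs(data, fs)
  tf <- timefreq_power(ep, 1, freqs = tf_freq_grid(), times = tf_time_grid())
  p80 <- tf$power[1, tf$freqs == 80, ]
  expect_lt((max(p80) - min(p80)) / mean(p80), 0.01)
  expect_equal(which.max(apply(tf$power[1, , ], 1, mean)),
               which(tf$freqs == 80))

  zero <- make_epochs(array(0, c(1, 1, n_t)), fs)
  tfz <- timefreq_power(zero, 1)
  expect_equal(max(abs(tfz$power)), 0)

  # window extending beyond the epoch is an error
  short <- make_epochs(array(0, c(1, 1, 1024)), fs, t0 = -0.25)
  expect_error(timefreq_power(short, 1, times = seq(-0.2, 0.7, 0.01)),
               "bounds")
})

test_that("normalization fixes the per-frequency grand mean at 1 and is scale invariant", {
  fs <- 512
  set.seed(33)
  data <- array(rnorm(8 * 1 * 512), c(8, 1, 512))
  ep <- make_epochs(data, fs, t0 = -0.5,
                    keep = c(rep(TRUE, 6), FALSE, FALSE))
  tf <- timefreq_power(ep, 1, window_s = 0.2, freqs = c(10, 40, 80),
                       times = seq(-0.3, 0.3, 0.05))
  nm <- normalize_power(tf)
  kept <- nm$trials$keep
  for (fi in seq_along(nm$freqs)) {
    expect_equal(mean(nm$power[kept, fi, ]), 1, tolerance = 1e-12)
  }
  expect_true(nm$normalized)
  expect_error(normalize_power(nm), "already")

  # scale invariance: doubling the raw signal leaves normalized power unchanged
  ep2 <- ep
  ep2$data <- ep2$data * 2
  tf2 <- timefreq_power(ep2, 1, window_s = 0.2, freqs = c(10, 40, 80),
                        times = seq(-0.3, 0.3, 0.05))
  nm2 <- normalize_power(tf2)
  expect_equal(nm2$power, nm$power, tolerance = 1e-12)
})

test_that("normalized 1/f-shaped input is flat across frequencies in expectation", {
  plan <- build_sequential_plan(stim_params())
  plan$events <- retained_trial_filter(plan$events, "sequential")
  sc <- synth_config(channels = data.frame(
    name = "s", archetype = "silent", n_pref = NA_integer_),
    line_amp_uv = c(`50` = 0, `100` = 0, `150` = 0), evoked_amp_uv = 0)
  sim <- simulate_run(plan, sc, seed = 44)
  ep <- epoch_data(sim$recording, sim$events)
  tf <- timefreq_power(ep, 1, freqs = seq(10, 110, 20))
  raw_means <- apply(tf$power, 2, mean)
  expect_gt(raw_means[1] / raw_means[6], 10)  # strongly 1/f before
  nm <- normalize_power(tf)
  norm_means <- apply(nm$power[nm$trials$keep, , ], 2, mean)
  expect_equal(max(abs(norm_means - 1)), 0, tolerance = 1e-9)
})

test_that("baseline correction zeroes the declared statistic per trial", {
  fs <- 512
  set.seed(35)
  data <- array(rnorm(6 * 1 * 512) + 5, c(6, 1, 512))
  ep <- make_epochs(data, fs, t0 = -0.5)
  tf <- normalize_power(timefreq_power(ep, 1, window_s = 0.2,
                                       freqs = c(20, 60),
                                       times = seq(-0.3, 0.3, 0.05)))
  bw <- baseline_correct(tf, "window", window = c(-0.3, -0.1))
  cols <- which(bw$times >= -0.3 - 1e-9 & bw$times <= -0.1 + 1e-9)
  for (ti in 1:6) {
    for (fi in 1:2) {
      expect_equal(mean(bw$power[ti, fi, cols]), 0, tolerance = 1e-12)
    }
  }
  expect_error(baseline_correct(bw, "window"), "already")
  expect_error(baseline_correct(timefreq_power(ep, 1, window_s = 0.2,
                                               freqs = 20,
                                               times = seq(-0.3, 0.3, 0.05)),
                                "window"),
               "normalized")

  bp <- baseline_correct(tf, "point", point = -0.3)
  expect_equal(unname(bp$power[, , 1]), matrix(0, 6, 2), tolerance = 1e-12)

  # a constant time course becomes exactly zero
  hfb_const <- make_hfb(matrix(3.3, 4, 91), tf_time_grid())
  out <- baseline_correct(hfb_const, "window")
  expect_equal(max(abs(out$timecourse)), 0)
  expect_equal(out$scalar, rep(0, 4))
})

test_that("HFB extraction averages exactly the in-band bins and keeps the scalar consistent", {
  fs <- 2048
  set.seed(36)
  data <- array(rnorm(3 * 1 * 3073), c(3, 1, 3073))
  ep <- make_epochs(data, fs)
  tf <- normalize_power(timefreq_power(ep, 1))
  h <- extract_hfb(tf, band = c(60, 120))
  expect_equal(h$n_bins, 31)
  bins <- which(tf$freqs >= 60 & tf$freqs <= 120)
  manual <- apply(tf$power[, bins, ], c(1, 3), mean)
  expect_equal(h$timecourse, manual)
  # the scalar equals the mean of the stored time course over the window
  cols <- which(h$times >= 0.1 - 1e-9 & h$times <= 0.35 + 1e-9)
  expect_equal(h$scalar, rowMeans(h$timecourse[, cols]))

  # degenerate single-bin band is the identity on that bin
  h4 <- extract_hfb(tf, band = c(4, 4))
  expect_equal(h4$timecourse, tf$power[, tf$freqs == 4, ] + 0)
  expect_equal(h4$n_bins, 1)

  expect_error(extract_hfb(tf, band = c(60, 200)), "outside")

  # constant in-band power v gives a constant-v time course
  tfc <- tf
  tfc$power[] <- 2.5
  hc <- extract_hfb(tfc)
  expect_equal(max(abs(hc$timecourse - 2.5)), 0)
})
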