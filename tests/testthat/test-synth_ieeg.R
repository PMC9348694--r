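test_that("tuning_amplitude follows the archetype response models", {
  sc <- synth_config(a_max = 20, sigma_log = 0.5, gamma = 1)
  # log-Gaussian peak sits exactly at the preferred numerosity
  expect_equal(tuning_amplitude(4, sc, "tuned", n_pref = 4), 20)
  # symmetry in log-numerosity about the preferred value
  expect_equal(tuning_amplitude(1, sc, "tuned", n_pref = 2),
               tuning_amplitude(4, sc, "tuned", n_pref = 2))
  # linear contrast-energy case
  expect_equal(tuning_amplitude(20, sc, "energy") /
                 tuning_amplitude(1, sc, "energy"), 20)
  expect_equal(tuning_amplitude(7, sc, "flat"), 20)
  expect_equal(tuning_amplitude(7, sc, "silent"), 0)
  expect_error(tuning_amplitude(7, sc, "sparkly"), "archetype")
  expect_error(tuning_amplitude(0, sc, "flat"), "positive")
})

test_that("simulation is reproducible from the seed and respects the duration cap", {
  plan <- build_sequential_plan(stim_params(n_sequence_repeats = 0))
  plan$events <- retained_trial_filter(plan$events, "sequential")
  sc <- synth_config(channels = data.frame(
    name = c("a", "b"), archetype = c("flat", "silent"),
    n_pref = NA_integer_))
  s1 <- simulate_run(plan, sc, seed = 4)
  s2 <- simulate_run(plan, sc, seed = 4)
  expect_identical(s1$recording$samples, s2$recording$samples)
  s3 <- simulate_run(plan, sc, seed = 5)
  expect_false(identical(s1$recording$samples, s3$recording$samples))

  tiny <- synth_config(max_duration_s = 1)
  expect_error(simulate_run(plan, tiny, seed = 1), "maximum")
})

test_that("an all-silent, noise-free configuration yields shaped background only", {
  plan <- build_sequential_plan(stim_params())
  plan$events <- retained_trial_filter(plan$events, "sequential")
  sc <- synth_config(
    channels = data.frame(name = "s", archetype = "silent",
                          n_pref = NA_integer_),
    evoked_amp_uv = 0, line_amp_uv = c(`50` = 0, `100` = 0, `150` = 0),
    common_mode_frac = 0
  )
  sim <- simulate_run(plan, sc, seed = 6)
  x <- sim$recording$samples[1, ]
  # frequency-domain shaping zeroes the DC bin, so the mean is exactly 0
  expect_equal(mean(x), 0, tolerance = 1e-8)
  expect_equal(sd(x), sc$bg_sd_uv, tolerance = 0.05 * sc$bg_sd_uv)
  expect_true(all(sim$truth$amplitude == 0))
})

test_that("silent-channel background has log-log spectral slope ~ -chi over 4-100 Hz", {
  plan <- build_sequential_plan(stim_params())  # 186 s of data
  plan$events <- retained_trial_filter(plan$events, "sequential")
  for (chi in c(1, 2)) {
    sc <- synth_config(
      channels = data.frame(name = "s", archetype = "silent",
                            n_pref = NA_integer_),
      chi = chi, evoked_amp_uv = 0,
      line_amp_uv = c(`50` = 0, `100` = 0, `150` = 0)
    )
    sim <- simulate_run(plan, sc, seed = 10 + chi)
    x <- sim$recording$samples[1, ]
    fs <- sim$recording$sample_rate_hz
    # Welch-style averaged periodogram over 2 s segments
    seg_len <- 2 * fs
    n_seg <- floor(length(x) / seg_len)
    psd <- 0
    for (k in seq_len(n_seg)) {
      seg <- x[((k - 1) * seg_len + 1):(k * seg_len)]
      psd <- psd + Mod(fft(seg))^2
    }
    freqs <- seq(0, fs, length.out = seg_len + 1)[1:seg_len]
    use <- freqs >= 4 & freqs <= 100
    fit <- lm(log(psd[use]) ~ log(freqs[use]))
    expect_equal(unname(coef(fit)[2]), -chi, tolerance = 0.2)
  }
})

test_that("averaging epochs of one condition recovers the injected evoked waveform", {
  plan <- build_sequential_plan(stim_params())
  plan$events <- retained_trial_filter(plan$events, "sequential")
  sc <- synth_config(
    channels = data.frame(name = "s", archetype = "silent",
                          n_pref = NA_integer_),
    evoked_amp_uv = 8, line_amp_uv = c(`50` = 0, `100` = 0, `150` = 0)
  )
  sim <- simulate_run(plan, sc, seed = 12)
  ep <- epoch_data(sim$recording, sim$events, window = c(-0.5, 1.0))
  resid_sd <- function(idx) {
    avg <- colMeans(ep$data[idx, 1, ])
    t_rel <- ep$times
    cond <- as.integer(ep$trials$trial_type[idx[1]])
    cix <- match(cond, c(1:7, 20))
    truth <- numecog:::evoked_waveform(t_rel, cix, 8)
    sd(avg - truth)
  }
  idx7 <- which(ep$trials$trial_type == "7" & ep$trials$keep)
  # residual shrinks roughly as 1/sqrt(N)
  r5 <- resid_sd(idx7[1:5])
  r20 <- resid_sd(idx7)
  expect_lt(r20, r5)
  expect_equal(r20, sd(sim$recording$samples[1, ]) / sqrt(20),
               tolerance = 0.5)
})

test_that("artifact injection flags an exact seeded subset and leaves others untouched", {
  plan <- build_sequential_plan(stim_params())
  ev <- retained_trial_filter(plan$events, "sequential")
  sc <- synth_config(channels = data.frame(
    name = "s", archetype = "silent", n_pref = NA_integer_))
  sim <- simulate_run(plan, sc, seed = 13)

  none <- inject_artifact_trials(sim$recording, ev, fraction = 0, seed = 1)
  expect_identical(none$recording$samples, sim$recording$samples)
  expect_false(any(none$artifact))

  out <- inject_artifact_trials(sim$recording, ev, fraction = 0.1, seed = 1)
  expect_equal(sum(out$artifact), round(0.1 * sum(ev$keep)))
  expect_equal(sum(out$artifact), 18)  # 10% of the 180 retained trials
  expect_true(all(ev$keep[out$artifact]))

  again <- inject_artifact_trials(sim$recording, ev, fraction = 0.1, seed = 1)
  expect_identical(out$artifact, again$artifact)
  expect_error(
    inject_artifact_trials(sim$recording, ev, fraction = 1.2, seed = 1),
    "fraction")
})
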