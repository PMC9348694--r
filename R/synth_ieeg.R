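#' Synthetic recording configuration
#'
#' Parameters of the synthetic raw-data generator. Each simulated channel
#' follows one of four response archetypes mirroring the response patterns
#' seen in intracranial numerosity recordings:
#' \describe{
#'   \item{tuned}{log-Gaussian numerosity tuning: burst amplitude
#'     `a_max * exp(-(ln n - ln n_pref)^2 / (2 sigma_log^2))`.}
#'   \item{energy}{monotonically increasing with numerosity (stimulus
#'     contrast energy): `a_max * (n / 20)^gamma`.}
#'   \item{flat}{equal response `a_max` to every numerosity.}
#'   \item{silent}{no stimulus-locked broadband response.}
#' }
#' Burst amplitudes are expressed in units of the background RMS within the
#' 60--120 Hz band, so `a_max = 1` injects a burst as strong as the
#' background high-frequency activity it rides on.
#'
#' @param channels Data frame with columns `name`, `archetype`
#'   (`"tuned"`, `"energy"`, `"flat"`, `"silent"`), `n_pref` (preferred
#'   numerosity; used by tuned channels), and optionally `label`
#'   (anatomical label, default `"parietal"`) and `category_amp`
#'   (relative response to category stimuli, default 0: numerosity-only).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param acq_band_hz Acquisition band edges (Hz); background noise is
#'   shaped inside this band.
#' @param a_max Peak burst amplitude, in units of in-band background RMS.
#' @param sigma_log Log-tuning width of tuned channels.
#' @param gamma Exponent of the energy archetype.
#' @param burst_latency_s,burst_rise_s,burst_duration_s Burst envelope:
#'   onset latency after stimulus onset, raised-cosine rise/fall time, and
#'   plateau duration (seconds).
#' @param hfb_band_hz Carrier band of the broadband bursts.
#' @param evoked_amp_uv Amplitude of the deterministic per-condition evoked
#'   waveform (microvolts); identical across trials of a condition.
#' @param chi Spectral exponent of the 1/f^chi background.
#' @param bg_sd_uv Broadband background standard deviation (microvolts).
#' @param common_mode_frac Fraction (0--1) of background variance shared
#'   across channels (removed by common-average referencing).
#' @param line_amp_uv Amplitudes (microvolts) of 50/100/150 Hz line noise.
#' @param jitter_sdlog SD of the lognormal per-trial burst-amplitude
#'   jitter (unit median).
#' @param artifact_amp_uv Amplitude of injected pre-stimulus artifacts.
#' @param max_duration_s Refuse to simulate runs longer than this.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(channels = data.frame(
                           name = c("ch1", "ch2"),
                           archetype = c("tuned", "silent"),
                           n_pref = c(4L, NA_integer_)
                         ),
                         sample_rate_hz = 2048,
                         acq_band_hz = c(0.15, 536),
                         a_max = 2.5,
                         sigma_log = 0.3,
                         gamma = 1,
                         burst_latency_s = 0.050,
                         burst_rise_s = 0.050,
                         burst_duration_s = 0.250,
                         hfb_band_hz = c(60, 120),
                         evoked_amp_uv = 5,
                         chi = 2,
                         bg_sd_uv = 20,
                         common_mode_frac = 0.3,
                         line_amp_uv = c(`50` = 5, `100` = 2, `150` = 1),
                         jitter_sdlog = 0.10,
                         artifact_amp_uv = 1500,
                         max_duration_s = 3600) {
  stopifnot(is.data.frame(channels),
            all(c("name", "archetype", "n_pref") %in% names(channels)))
  if (!all(channels$archetype %in% c("tuned", "energy", "flat", "silent"))) {
    stop("unknown channel archetype", call. = FALSE)
  }
  if (anyDuplicated(channels$name) > 0) {
    stop_field("channels", "channel names must be unique")
  }
  if (is.null(channels$label)) channels$label <- "parietal"
  if (is.null(channels$category_amp)) channels$category_amp <- 0
  check_scalar_pos(sample_rate_hz, "sample_rate_hz")
  check_range2(acq_band_hz, "acq_band_hz")
  check_range2(hfb_band_hz, "hfb_band_hz")
  if (a_max < 0) stop_field("a_max", "must be nonnegative")
  check_scalar_pos(sigma_log, "sigma_log")
  if (chi < 0) stop_field("chi", "must be nonnegative")
  if (common_mode_frac < 0 || common_mode_frac > 1) {
    stop_field("common_mode_frac", "must lie in [0, 1]")
  }
  tuned <- channels$archetype == "tuned"
  if (any(tuned & (is.na(channels$n_pref) | channels$n_pref < 1))) {
    stop_field("channels$n_pref", "tuned channels need a positive n_pref")
  }
  structure(
    list(
      channels = channels,
      sample_rate_hz = sample_rate_hz,
      acq_band_hz = acq_band_hz,
      a_max = a_max, sigma_log = sigma_log, gamma = gamma,
      burst_latency_s = burst_latency_s, burst_rise_s = burst_rise_s,
      burst_duration_s = burst_duration_s,
      hfb_band_hz = hfb_band_hz,
      evoked_amp_uv = evoked_amp_uv,
      chi = chi, bg_sd_uv = bg_sd_uv,
      common_mode_frac = common_mode_frac,
      line_amp_uv = line_amp_uv,
      jitter_sdlog = jitter_sdlog,
      artifact_amp_uv = artifact_amp_uv,
      max_duration_s = max_duration_s
    ),
    class = "synth_config"
  )
}

#' Burst amplitude for a numerosity under a response archetype
#'
#' @param n Numerosity level (positive integer).
#' @param config A [synth_config()].
#' @param archetype One of `"tuned"`, `"energy"`, `"flat"`, `"silent"`.
#' @param n_pref Preferred numerosity (tuned archetype).
#' @return Amplitude scalar in units of in-band background RMS.
#' @export
tuning_amplitude <- function(n, config, archetype, n_pref = NA) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.numeric(n) || any(n < 1)) stop("`n` must be positive", call. = FALSE)
  switch(archetype,
    tuned = {
      if (is.na(n_pref)) stop("tuned archetype needs n_pref", call. = FALSE)
      config$a_max *
        exp(-(log(n) - log(n_pref))^2 / (2 * config$sigma_log^2))
    },
    energy = config$a_max * (n / 20)^config$gamma,
    flat = rep(config$a_max, length(n)),
    silent = rep(0, length(n)),
    stop(sprintf("unknown archetype '%s'", archetype), call. = FALSE)
  )
}

# 1/f^chi-shaped Gaussian noise via frequency-domain amplitude scaling of
# white noise, restricted to the acquisition band. Returns unit-SD series.
shaped_noise <- function(n, fs, chi, band) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, fs - freqs)   # fold to two-sided frequency magnitude
  amp <- numeric(n)
  inb <- freqs >= band[1] & freqs <= band[2]
  amp[inb] <- freqs[inb]^(-chi / 2)
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Fraction of the shaped-background variance lying inside `sub` of `band`.
inband_variance_fraction <- function(chi, band, sub) {
  pw <- function(lo, hi) {
    if (abs(chi - 1) < 1e-12) log(hi / lo) else
      (hi^(1 - chi) - lo^(1 - chi)) / (1 - chi)
  }
  pw(sub[1], sub[2]) / pw(band[1], band[2])
}

# Band-limited unit-SD noise carrier for broadband bursts.
burst_carrier <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# Raised-cosine burst envelope evaluated on a sample grid (seconds after
# stimulus onset).
burst_envelope <- function(t, latency, rise, duration) {
  u <- t - latency
  env <- numeric(length(t))
  ix <- u >= 0 & u < rise
  env[ix] <- 0.5 * (1 - cos(pi * u[ix] / rise))
  ix <- u >= rise & u < rise + duration
  env[ix] <- 1
  ix <- u >= rise + duration & u < 2 * rise + duration
  env[ix] <- 0.5 * (1 + cos(pi * (u[ix] - rise - duration) / rise))
  env
}

# Deterministic evoked waveform for a condition: a damped 10 Hz wavelet
# whose amplitude depends weakly on the condition index so that conditions
# are distinguishable in the average.
evoked_waveform <- function(t, cond_index, amp_uv) {
  scale <- amp_uv * (1 + 0.05 * cond_index)
  out <- numeric(length(t))
  ix <- t >= 0 & t <= 0.5
  out[ix] <- scale * sin(2 * pi * 10 * t[ix]) * exp(-t[ix] / 0.1)
  out
}

#' Simulate a raw multichannel recording for a stimulus plan
#'
#' Generates, per channel, a 1/f^chi Gaussian background mixed with a
#' shared common-mode series, sinusoidal line noise at 50/100/150 Hz, a
#' deterministic per-condition evoked waveform, and stimulus-locked
#' broadband bursts (band-limited 60--120 Hz noise under a raised-cosine
#' envelope) whose amplitude follows the channel's response archetype with
#' lognormal per-trial jitter. Fully reproducible from `seed`.
#'
#' @param plan A `stimulus_plan`.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A list with elements `recording` (a `raw_recording`), `events`
#'   (the plan's events), and `truth` (ground-truth channel table and
#'   per-trial injected amplitude matrix, channels x trials).
#' @export
simulate_run <- function(plan, config, seed) {
  stopifnot(inherits(plan, "stimulus_plan"), inherits(config, "synth_config"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (plan$total_duration_s > config$max_duration_s) {
    stop(sprintf("plan duration %.1f s exceeds configured maximum %.1f s",
                 plan$total_duration_s, config$max_duration_s), call. = FALSE)
  }
  fs <- config$sample_rate_hz
  n_samp <- as.integer(round(plan$total_duration_s * fs))
  chans <- config$channels
  n_ch <- nrow(chans)
  ev <- plan$events
  n_tr <- nrow(ev)
  tvec <- (seq_len(n_samp) - 1) / fs

  # burst amplitude in microvolts: archetype tuning x in-band background RMS
  inband_rms <- config$bg_sd_uv *
    sqrt(inband_variance_fraction(config$chi, config$acq_band_hz,
                                  config$hfb_band_hz))
  is_cat <- plan$run_kind == "category"
  cond_levels <- if (is_cat) plan$params$category_levels else
    as.character(plan$params$numerosity_levels)

  amp <- matrix(0, n_ch, max(n_tr, 1))
  samples <- matrix(0, n_ch, n_samp)

  with_seed(derive_seed(seed, "simulate_run"), {
    common <- shaped_noise(n_samp, fs, config$chi, config$acq_band_hz)
    line <- numeric(n_samp)
    for (k in seq_along(config$line_amp_uv)) {
      f <- as.numeric(names(config$line_amp_uv)[k])
      if (is.na(f)) f <- 50 * k
      line <- line + config$line_amp_uv[[k]] *
        sin(2 * pi * f * tvec + stats::runif(1, 0, 2 * pi))
    }

    # per-trial envelope support indices precomputed once
    env_len_s <- config$burst_latency_s + 2 * config$burst_rise_s +
      config$burst_duration_s
    env_nsamp <- as.integer(ceiling(env_len_s * fs)) + 1L

    for (ci in seq_len(n_ch)) {
      bg <- shaped_noise(n_samp, fs, config$chi, config$acq_band_hz)
      rho <- config$common_mode_frac
      x <- config$bg_sd_uv * (sqrt(1 - rho^2) * bg + rho * common) + line

      # per-condition amplitude for this channel
      arche <- chans$archetype[ci]
      if (n_tr > 0) {
        if (is_cat) {
          base_amp <- rep(config$a_max * chans$category_amp[ci],
                          length(cond_levels))
        } else {
          base_amp <- tuning_amplitude(as.numeric(cond_levels), config,
                                       arche, chans$n_pref[ci])
        }
        names(base_amp) <- cond_levels
        jit <- stats::rlnorm(n_tr, 0, config$jitter_sdlog)
        amp[ci, seq_len(n_tr)] <- base_amp[ev$trial_type] * jit

        carrier <- burst_carrier(n_samp, fs, config$hfb_band_hz)
        gate <- numeric(n_samp)
        for (ti in seq_len(n_tr)) {
          i0 <- time_to_sample(ev$onset[ti], fs) + 1L
          idx <- i0:min(i0 + env_nsamp - 1L, n_samp)
          rel_t <- (idx - i0) / fs
          gate[idx] <- gate[idx] + amp[ci, ti] *
            burst_envelope(rel_t, config$burst_latency_s,
                           config$burst_rise_s, config$burst_duration_s)
        }
        x <- x + inband_rms * gate * carrier

        # deterministic evoked component, identical across a condition
        for (ti in seq_len(n_tr)) {
          cix <- match(ev$trial_type[ti], cond_levels)
          i0 <- time_to_sample(ev$onset[ti], fs) + 1L
          idx <- i0:min(i0 + as.integer(0.5 * fs), n_samp)
          x[idx] <- x[idx] +
            evoked_waveform((idx - i0) / fs, cix, config$evoked_amp_uv)
        }
      }
      samples[ci, ] <- x
    }
  })

  rec <- raw_recording(
    samples = samples,
    sample_rate_hz = fs,
    channels = data.frame(
      name = chans$name,
      label = chans$label,
      include = TRUE,
      kind = "seeg",
      stringsAsFactors = FALSE
    ),
    acq_band_hz = config$acq_band_hz
  )
  truth <- list(
    channels = chans,
    amplitude = amp,
    artifact = rep(FALSE, n_tr)
  )
  list(recording = rec, events = ev, truth = truth)
}

#' Inject artifact trials into a recording
#'
#' Adds, on every channel, a large step-onset exponentially decaying
#' transient shortly before stimulus onset for a seeded subset of retained
#' trials. The sharp edge leaks broadband power into the 60--120 Hz band,
#' so flagged trials exceed the pre-stimulus quality-control thresholds by
#' construction.
#'
#' @param recording A `raw_recording`.
#' @param events Events data frame (uses `keep` to choose candidates).
#' @param fraction Fraction of retained trials to corrupt (exact count,
#'   `round(fraction * n_retained)`).
#' @param seed Integer seed.
#' @param amp_uv Artifact amplitude (microvolts).
#' @param t0_s Artifact onset relative to stimulus onset (seconds).
#' @param tau_s Decay time constant (seconds).
#' @return A list with the modified `recording` and logical `artifact`
#'   flags (one per event row).
#' @export
inject_artifact_trials <- function(recording, events, fraction, seed,
                                   amp_uv = 1500, t0_s = -0.12,
                                   tau_s = 0.03) {
  stopifnot(inherits(recording, "raw_recording"))
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  n_ev <- nrow(events)
  flags <- rep(FALSE, n_ev)
  cand <- which(events$keep)
  k <- as.integer(round(fraction * length(cand)))
  if (k == 0) {
    return(list(recording = recording, artifact = flags))
  }
  fs <- recording$sample_rate_hz
  n_samp <- ncol(recording$samples)
  n_ch <- nrow(recording$samples)
  with_seed(derive_seed(seed, "artifacts"), {
    pick <- sample(cand, k)
    # channel-heterogeneous amplitudes (random scale and sign) so the
    # transient survives common-average referencing, as real electrode
    # pops do
    ch_scale <- stats::runif(n_ch, 0.5, 1.5) *
      sample(c(-1, 1), n_ch, replace = TRUE)
    flags[pick] <- TRUE
    dur_n <- as.integer(round(6 * tau_s * fs))
    for (ti in pick) {
      i0 <- time_to_sample(events$onset[ti] + t0_s, fs) + 1L
      idx <- max(1L, i0):min(i0 + dur_n, n_samp)
      rel_t <- (idx - i0) / fs
      wave <- amp_uv * exp(-rel_t / tau_s) * (rel_t >= 0)
      recording$samples[, idx] <- recording$samples[, idx] +
        ch_scale %o% wave
    }
  })
  list(recording = recording, artifact = flags)
}
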