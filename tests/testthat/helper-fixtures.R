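# Shared fixture builders. Everything is generated in code at test time;
# no stored data files.

# Construct a minimal epoch_set directly from an array (trials x channels
# x time), bypassing the epoching machinery, for unit tests of the
# spectral stages.
make_epochs <- function(data, fs, trial_type = NULL, keep = NULL,
                        t0 = -0.5) {
  n_tr <- dim(data)[1]
  if (is.null(trial_type)) trial_type <- rep("1", n_tr)
  if (is.null(keep)) keep <- rep(TRUE, n_tr)
  n_ch <- dim(data)[2]
  structure(
    list(
      data = data,
      times = t0 + (seq_len(dim(data)[3]) - 1) / fs,
      trials = data.frame(
        onset = seq_len(n_tr), duration = 0.25,
        trial_type = as.character(trial_type),
        block_index = NA_integer_, within_block_index = NA_integer_,
        is_oddball = FALSE, keep = keep,
        stringsAsFactors = FALSE
      ),
      channels = data.frame(
        name = sprintf("ch%d", seq_len(n_ch)), label = "other",
        include = TRUE, kind = "seeg", stringsAsFactors = FALSE
      ),
      sample_rate_hz = fs,
      notched = TRUE, referenced = TRUE
    ),
    class = "epoch_set"
  )
}

# Independent brute-force oracle for the tapered sliding-window power:
# plain loops and a direct complex-exponential sum, sharing no code with
# timefreq_power().
naive_tf_power <- function(epochs, channel, window_s, freqs, times) {
  fs <- epochs$sample_rate_hz
  wlen <- round(window_s * fs)
  n <- 0:(wlen - 1)
  taper <- 0.5 * (1 - cos(2 * pi * n / (wlen - 1)))
  n_tr <- dim(epochs$data)[1]
  out <- array(NA_real_, c(n_tr, length(freqs), length(times)))
  epoch_start_sample <- round(epochs$times[1] * fs)
  for (ti in seq_len(n_tr)) {
    for (wi in seq_along(times)) {
      centre <- round(times[wi] * fs)
      first <- centre - (wlen %/% 2) - epoch_start_sample + 1
      seg <- epochs$data[ti, channel, first:(first + wlen - 1)]
      for (fi in seq_along(freqs)) {
        coef <- sum(seg * taper * exp(-2i * pi * freqs[fi] * n / fs))
        out[ti, fi, wi] <- Mod(coef)^2
      }
    }
  }
  out
}

# A small synthetic hfb_response for QC tests, built by hand.
make_hfb <- function(timecourse, times, trial_type = NULL, keep = NULL,
                     normalized = TRUE, baseline_corrected = FALSE,
                     tuning_window = c(0.1, 0.35)) {
  n_tr <- nrow(timecourse)
  if (is.null(trial_type)) trial_type <- rep("1", n_tr)
  if (is.null(keep)) keep <- rep(TRUE, n_tr)
  structure(
    list(
      timecourse = timecourse,
      times = times,
      scalar = numecog:::hfb_window_scalar(timecourse, times, tuning_window),
      tuning_window_s = tuning_window,
      band = c(60, 120), n_bins = 31,
      trials = data.frame(
        onset = seq_len(n_tr), duration = 0.25,
        trial_type = as.character(trial_type),
        is_oddball = FALSE, keep = keep, stringsAsFactors = FALSE
      ),
      channel = "ch1",
      normalized = normalized, baseline_corrected = baseline_corrected
    ),
    class = "hfb_response"
  )
}

# Default time grid used across tests.
tf_time_grid <- function() seq(-0.2, 0.7, by = 0.01)
tf_freq_grid <- function() seq(2, 122, by = 2)
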