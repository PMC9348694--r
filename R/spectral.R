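#' Remove the evoked (phase-locked) signal per condition
#'
#' For each condition, the mean across that condition's retained trials is
#' subtracted from every trial of the condition, per channel and sample,
#' so that subsequent spectral power reflects induced (non-phase-locked)
#' activity only.
#'
#' @param epochs An `epoch_set`.
#' @return The `epoch_set` with per-condition means removed.
#' @export
remove_evoked <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- unique(epochs$trials$trial_type)
  for (cond in conds) {
    in_cond <- epochs$trials$trial_type == cond
    kept <- in_cond & epochs$trials$keep
    if (sum(kept) < 2) {
      stop(sprintf(
        "condition '%s' has %d retained trial(s); need at least 2 to estimate the evoked signal",
        cond, sum(kept)), call. = FALSE)
    }
    m <- apply(epochs$data[kept, , , drop = FALSE], c(2, 3), mean)
    for (ti in which(in_cond)) {
      epochs$data[ti, , ] <- epochs$data[ti, , ] - m
    }
  }
  epochs$evoked_removed <- TRUE
  epochs
}

#' Sliding-window Hanning-tapered spectral power
#'
#' For one channel, computes power at each requested frequency and window
#' centre: the 300 ms (default) window around the centre is multiplied by
#' a symmetric Hanning taper and projected onto a complex exponential at
#' exactly the requested frequency (a direct discrete Fourier inner
#' product, so the 2 Hz grid is exact regardless of the window's native
#' frequency resolution); the squared magnitude is stored. No
#' normalization is applied here.
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel name or index.
#' @param window_s Sliding-window width (seconds).
#' @param freqs Frequency grid (Hz); default 2--122 Hz in 2 Hz steps.
#' @param times Window-centre grid (seconds relative to onset); default
#'   -0.2 to +0.7 s in 10 ms steps.
#' @return A `tf_power` object: `power` (trials x frequencies x times),
#'   grids, trial metadata, and state flags.
#' @export
timefreq_power <- function(epochs, channel = 1, window_s = 0.300,
                           freqs = seq(2, 122, by = 2),
                           times = seq(-0.2, 0.7, by = 0.010)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(channel)) {
    channel <- match(channel, epochs$channels$name)
    if (is.na(channel)) stop("unknown channel name", call. = FALSE)
  }
  fs <- epochs$sample_rate_hz
  wlen <- as.integer(round(window_s * fs))
  # half-open window extent centred on the grid time
  off_lo <- -(wlen %/% 2)
  off_hi <- off_lo + wlen - 1L
  epoch_lo <- time_to_sample(epochs$times[1], fs)
  n_t_epoch <- length(epochs$times)
  centre <- time_to_sample(times, fs)
  lo <- centre + off_lo - epoch_lo + 1L
  hi <- centre + off_hi - epoch_lo + 1L
  if (any(lo < 1L) || any(hi > n_t_epoch)) {
    stop(sprintf(
      "sliding window (width %g s) exceeds epoch bounds at centre(s) %s s",
      window_s,
      paste(times[lo < 1L | hi > n_t_epoch], collapse = ", ")),
      call. = FALSE)
  }
  taper <- 0.5 * (1 - cos(2 * pi * (0:(wlen - 1)) / (wlen - 1)))
  phase <- outer((0:(wlen - 1)) / fs, 2 * pi * freqs)
  cos_b <- taper * cos(phase)
  sin_b <- taper * sin(phase)

  n_tr <- dim(epochs$data)[1]
  pow <- array(0, dim = c(n_tr, length(freqs), length(times)))
  x <- epochs$data[, channel, , drop = TRUE]
  if (n_tr == 1) x <- matrix(x, nrow = 1)
  for (wi in seq_along(times)) {
    seg <- x[, lo[wi]:hi[wi], drop = FALSE]
    pow[, , wi] <- (seg %*% cos_b)^2 + (seg %*% sin_b)^2
  }
  structure(
    list(
      power = pow,
      freqs = freqs,
      times = times,
      trials = epochs$trials,
      channel = epochs$channels$name[channel],
      window_s = window_s,
      taper = "hanning",
      normalized = FALSE,
      baseline_corrected = FALSE
    ),
    class = "tf_power"
  )
}

#' Normalize power per frequency
#'
#' Divides each (trial, frequency, time) value by the mean power at that
#' frequency over all retained trials and all time points, so every
#' frequency contributes equally to band averages despite the 1/f shape
#' of the raw spectrum.
#'
#' @param power A `tf_power`.
#' @return The `tf_power`, normalized, with `normalized = TRUE`.
#' @export
normalize_power <- function(power) {
  stopifnot(inherits(power, "tf_power"))
  if (power$normalized) stop("power is already normalized", call. = FALSE)
  kept <- power$trials$keep
  if (!any(kept)) stop("no retained trials", call. = FALSE)
  fmean <- apply(power$power[kept, , , drop = FALSE], 2, mean)
  if (any(fmean <= 0)) {
    stop(sprintf("zero mean power at frequency %g Hz",
                 power$freqs[which(fmean <= 0)[1]]), call. = FALSE)
  }
  power$power <- sweep(power$power, 2, fmean, "/")
  power$normalized <- TRUE
  power
}

#' Baseline-correct normalized power or an HFB response
#'
#' Window mode subtracts, per trial (and per frequency for
#' time--frequency input), the mean over the pre-stimulus baseline window
#' (default -200 to -50 ms). Point mode subtracts the value at a single
#' pre-trigger time (default -200 ms), used when the true stimulus onset
#' is shifted by an unknown fixed trigger delay.
#'
#' @param x A `tf_power` or `hfb_response` (normalized, not yet
#'   baseline-corrected).
#' @param mode `"window"` or `"point"`.
#' @param window Baseline window (seconds), window mode.
#' @param point Baseline time (seconds), point mode.
#' @return The input object, baseline-corrected.
#' @export
baseline_correct <- function(x, mode = c("window", "point"),
                             window = c(-0.2, -0.05), point = -0.2) {
  mode <- match.arg(mode)
  if (!x$normalized) {
    stop("baseline correction expects normalized power", call. = FALSE)
  }
  if (x$baseline_corrected) {
    stop("input is already baseline-corrected", call. = FALSE)
  }
  tol <- 1e-9
  if (mode == "window") {
    cols <- which(x$times >= window[1] - tol & x$times <= window[2] + tol)
    if (length(cols) == 0) {
      stop("baseline window lies outside the time grid", call. = FALSE)
    }
  } else {
    cols <- which(abs(x$times - point) < tol)
    if (length(cols) != 1) {
      stop("baseline point is not on the time grid", call. = FALSE)
    }
  }
  if (inherits(x, "tf_power")) {
    base <- apply(x$power[, , cols, drop = FALSE], c(1, 2), mean)
    x$power <- x$power - array(base, dim = dim(x$power))
  } else if (inherits(x, "hfb_response")) {
    base <- rowMeans(x$timecourse[, cols, drop = FALSE])
    x$timecourse <- x$timecourse - base
    x$scalar <- hfb_window_scalar(x$timecourse, x$times, x$tuning_window_s)
  } else {
    stop("unsupported input type", call. = FALSE)
  }
  x$baseline_corrected <- TRUE
  x$baseline <- list(mode = mode,
                     window = if (mode == "window") window else point)
  x
}

hfb_window_scalar <- function(tc, times, win) {
  tol <- 1e-9
  cols <- which(times >= win[1] - tol & times <= win[2] + tol)
  rowMeans(tc[, cols, drop = FALSE])
}

#' Extract the high-frequency-band response
#'
#' Unweighted mean of normalized power over the frequency bins inside the
#' band (edges inclusive; 31 bins for 60--120 Hz on the 2 Hz grid), per
#' trial and time point, plus the per-trial scalar response: the mean of
#' the time course over the tuning window.
#'
#' @param power A normalized `tf_power`.
#' @param band Band edges in Hz, inclusive.
#' @param tuning_window_s Window (seconds after onset) over which the
#'   scalar response is averaged.
#' @return An `hfb_response`: `timecourse` (trials x times), `scalar`
#'   (per trial), trial metadata and state flags.
#' @export
extract_hfb <- function(power, band = c(60, 120),
                        tuning_window_s = c(0.100, 0.350)) {
  stopifnot(inherits(power, "tf_power"))
  if (!power$normalized) {
    stop("extract_hfb expects normalized power", call. = FALSE)
  }
  tol <- 1e-9
  bins <- which(power$freqs >= band[1] - tol & power$freqs <= band[2] + tol)
  if (length(bins) == 0 || band[1] < min(power$freqs) - tol ||
      band[2] > max(power$freqs) + tol) {
    stop(sprintf("band [%g, %g] Hz lies outside the frequency grid",
                 band[1], band[2]), call. = FALSE)
  }
  tc <- apply(power$power[, bins, , drop = FALSE], c(1, 3), mean)
  if (is.null(dim(tc))) tc <- matrix(tc, nrow = 1)
  structure(
    list(
      timecourse = tc,
      times = power$times,
      scalar = hfb_window_scalar(tc, power$times, tuning_window_s),
      tuning_window_s = tuning_window_s,
      band = band,
      n_bins = length(bins),
      trials = power$trials,
      channel = power$channel,
      normalized = power$normalized,
      baseline_corrected = power$baseline_corrected
    ),
    class = "hfb_response"
  )
}
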