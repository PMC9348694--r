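#' Notch-filter line noise
#'
#' Zero-phase (forward--backward) Butterworth band-stop filtering at each
#' line frequency, with a total stop-band width of `width_hz` centred on
#' the line. Removes 50 Hz mains interference and its 100/150 Hz
#' harmonics while leaving the passband essentially untouched.
#'
#' @param recording A [raw_recording()].
#' @param line_freqs Stop-band centre frequencies (Hz).
#' @param width_hz Total stop-band width (Hz).
#' @param order Butterworth prototype order per stop band (the effective
#'   band-stop order is twice this, and forward--backward filtering
#'   squares the magnitude response).
#' @return The recording, filtered, with `notched = TRUE`.
#' @export
notch_filter <- function(recording, line_freqs = c(50, 100, 150),
                         width_hz = 3, order = 2) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$sample_rate_hz
  if (fs <= 2 * max(line_freqs)) {
    stop(sprintf(
      "sampling rate %g Hz violates the Nyquist limit for a %g Hz stop band",
      fs, max(line_freqs)), call. = FALSE)
  }
  x <- recording$samples
  for (f0 in line_freqs) {
    edges <- c(f0 - width_hz / 2, f0 + width_hz / 2) / (fs / 2)
    bf <- signal::butter(order, edges, type = "stop")
    for (ci in seq_len(nrow(x))) {
      x[ci, ] <- signal::filtfilt(bf, x[ci, ])
    }
  }
  recording$samples <- x
  recording$notched <- TRUE
  recording
}

#' Re-reference to the common average of included channels
#'
#' At every sample, the mean over the included channels is subtracted
#' from each included channel. Excluded channels pass through untouched.
#'
#' @param recording A [raw_recording()].
#' @param selection Character vector of channel names to include, or
#'   `NULL` to use the recording's `include` flags.
#' @return The recording, re-referenced, with `referenced = TRUE`.
#' @export
common_average_reference <- function(recording, selection = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  if (is.null(selection)) {
    inc <- which(recording$channels$include)
  } else {
    unknown <- setdiff(selection, recording$channels$name)
    if (length(unknown) > 0) {
      stop(sprintf("selection names unknown channels: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    inc <- which(recording$channels$name %in% selection)
  }
  if (length(inc) == 0) {
    stop("common-average reference needs a nonempty channel selection",
         call. = FALSE)
  }
  if (length(inc) == 1) {
    warning("common-average reference over a single channel zeroes it")
  }
  avg <- colMeans(recording$samples[inc, , drop = FALSE])
  recording$samples[inc, ] <- sweep(
    recording$samples[inc, , drop = FALSE], 2, avg
  )
  recording$channels$include <- seq_len(nrow(recording$channels)) %in% inc
  recording$reference <- "common average"
  recording$referenced <- TRUE
  recording
}

#' Epoch a recording around stimulus onsets
#'
#' Cuts one fixed window per event, time-locked to stimulus onset. Onset
#' sample indices are computed by rounding `onset * rate` half away from
#' zero; a trigger delay is carried as a uniform integer sample shift
#' `round(trigger_offset_s * rate)` applied to every onset (the delayed
#' trigger is fixed across the run). Epoching copies raw samples
#' verbatim; no filtering happens here.
#'
#' @param recording A [raw_recording()].
#' @param events Events data frame (onset/duration in seconds).
#' @param window Epoch window in seconds relative to onset, e.g.
#'   `c(-0.5, 1.0)`; endpoints inclusive on the sample grid.
#' @param trigger_offset_s Fixed trigger delay (seconds).
#' @return An `epoch_set`: `data` (trials x channels x time array),
#'   `times` (seconds relative to onset), `trials` (event metadata with
#'   `keep` flags), `sample_rate_hz`, and provenance flags.
#' @export
epoch_data <- function(recording, events, window = c(-0.5, 1.0),
                       trigger_offset_s = 0) {
  stopifnot(inherits(recording, "raw_recording"))
  check_range2(window, "window")
  fs <- recording$sample_rate_hz
  n_samp <- ncol(recording$samples)
  shift <- time_to_sample(trigger_offset_s, fs)
  onset_idx <- time_to_sample(events$onset, fs) + shift
  s_lo <- time_to_sample(window[1], fs)
  s_hi <- time_to_sample(window[2], fs)
  lo <- onset_idx + s_lo + 1L   # 1-based sample indices
  hi <- onset_idx + s_hi + 1L
  bad <- which(lo < 1L | hi > n_samp)
  if (length(bad) > 0) {
    stop(sprintf(
      "epoch window [%g, %g] s exceeds recording bounds for event(s) %s",
      window[1], window[2], paste(utils::head(bad, 10), collapse = ", ")),
      call. = FALSE)
  }
  n_tr <- nrow(events)
  n_ch <- nrow(recording$samples)
  n_t <- s_hi - s_lo + 1L
  data <- array(0, dim = c(n_tr, n_ch, n_t))
  for (ti in seq_len(n_tr)) {
    data[ti, , ] <- recording$samples[, lo[ti]:hi[ti], drop = FALSE]
  }
  trials <- events
  if (is.null(trials$keep)) trials$keep <- TRUE
  structure(
    list(
      data = data,
      times = (s_lo:s_hi) / fs,
      trials = trials,
      channels = recording$channels,
      sample_rate_hz = fs,
      notched = recording$notched,
      referenced = recording$referenced
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples (%.3f to %.3f s @ %g Hz)\n",
    d[1], d[2], d[3], x$times[1], x$times[length(x$times)],
    x$sample_rate_hz
  ))
  cat(sprintf("  kept trials: %d/%d | notched: %s | re-referenced: %s\n",
              sum(x$trials$keep), d[1], x$notched, x$referenced))
  invisible(x)
}
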