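#' Raw multichannel recording container
#'
#' @param samples Channels x samples voltage matrix in microvolts.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param channels Data frame with columns `name`, `label` (anatomical:
#'   `"parietal"`, `"occipital"`, `"temporal"`, `"other"`), `include`
#'   (logical) and `kind` (`"grid"` or `"seeg"`). Defaults are generated
#'   if omitted.
#' @param reference Free-text description of the reference.
#' @param acq_band_hz Acquisition band edges (Hz).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sample_rate_hz, channels = NULL,
                          reference = "mastoid", acq_band_hz = c(0.15, 536)) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (is.null(channels)) {
    channels <- data.frame(
      name = sprintf("ch%d", seq_len(nrow(samples))),
      label = "other", include = TRUE, kind = "seeg",
      stringsAsFactors = FALSE
    )
  }
  if (nrow(channels) != nrow(samples)) {
    stop("channel table row count must equal sample matrix row count",
         call. = FALSE)
  }
  check_scalar_pos(sample_rate_hz, "sample_rate_hz")
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      channels = channels,
      reference = reference,
      acq_band_hz = acq_band_hz,
      notched = FALSE,
      referenced = FALSE
    ),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
    ncol(x$samples) / x$sample_rate_hz
  ))
  cat(sprintf("  reference: %s | notched: %s | re-referenced: %s\n",
              x$reference, x$notched, x$referenced))
  invisible(x)
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to a 16-bit EDF file
#'
#' Standard European-Data-Format output: one-second data records, 16-bit
#' little-endian samples, configurable physical range (the only lossy step
#' is the 16-bit quantization). If the recording length is not a whole
#' number of seconds the final record is zero-padded (with a warning).
#'
#' @param recording A [raw_recording()].
#' @param path Output file path.
#' @param physical_max_uv Physical range (+/- microvolts). The default
#'   3276.7 gives 0.1 uV resolution.
#' @return `path`, invisibly.
#' @export
write_raw_edf <- function(recording, path, physical_max_uv = 3276.7) {
  stopifnot(inherits(recording, "raw_recording"))
  x <- recording$samples
  if (nrow(x) == 0) stop("recording has no channels", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  if (max(abs(x)) > physical_max_uv) {
    stop(sprintf(
      "samples exceed the physical range +/-%.1f uV (max |x| = %.1f); no silent clipping",
      physical_max_uv, max(abs(x))), call. = FALSE)
  }
  fs <- recording$sample_rate_hz
  if (fs != round(fs)) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(fs)
  n_ch <- nrow(x)
  n_samp <- ncol(x)
  n_rec <- as.integer(ceiling(n_samp / fs))
  if (n_rec * fs != n_samp) {
    warning("recording length is not a whole number of seconds; final EDF record zero-padded")
    x <- cbind(x, matrix(0, n_ch, n_rec * fs - n_samp))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_ascii(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("Startdate 01-JAN-2026 X X %s", "numecog"), 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + n_ch), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(n_ch, 4)
  for (nm in recording$channels$name) wr(nm, 16)
  for (i in seq_len(n_ch)) wr("intracranial", 80)
  for (i in seq_len(n_ch)) wr("uV", 8)
  for (i in seq_len(n_ch)) wr(sprintf("%g", -physical_max_uv), 8)
  for (i in seq_len(n_ch)) wr(sprintf("%g", physical_max_uv), 8)
  for (i in seq_len(n_ch)) wr("-32768", 8)
  for (i in seq_len(n_ch)) wr("32767", 8)
  for (i in seq_len(n_ch)) {
    wr(sprintf("BP:%g-%gHz", recording$acq_band_hz[1],
               recording$acq_band_hz[2]), 80)
  }
  for (i in seq_len(n_ch)) wr(fs, 8)
  for (i in seq_len(n_ch)) wr("", 32)

  # inverse of the EDF affine phys = physmin + (dig - digmin) * range ratio,
  # so reading back lands within half a quantization step
  gain <- 65535 / (2 * physical_max_uv)
  dig <- matrix(
    as.integer(pmin(32767, round_half_away((x + physical_max_uv) * gain) - 32768)),
    n_ch
  )
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    # records are channel-blocked: all samples of channel 1, then 2, ...
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a raw_recording
#'
#' @param path EDF file path.
#' @param resample If channels have differing sampling rates, linearly
#'   resample them to the fastest rate instead of erroring.
#' @return A [raw_recording()] in microvolts. Channel metadata (anatomical
#'   label, include flag) is not part of EDF; attach it from a channels
#'   table ([read_channels_tsv()]).
#' @export
read_raw_edf <- function(path, resample = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") {
    stop(sprintf("malformed EDF header in %s (version field '%s')",
                 path, version), call. = FALSE)
  }
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  n_ch <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, n_ch)) || n_ch < 1) {
    stop(sprintf("malformed EDF header in %s", path), call. = FALSE)
  }
  rdv <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  prefilter <- rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    stop(sprintf("malformed EDF signal headers in %s", path), call. = FALSE)
  }
  if (length(unique(spr)) > 1 && !resample) {
    off <- labels[spr != max(spr)]
    stop(sprintf(
      "channels with differing sampling rates (%s); set resample = TRUE to interpolate",
      paste(off, collapse = ", ")), call. = FALSE)
  }

  raw <- vector("list", n_ch)
  for (i in seq_len(n_ch)) raw[[i]] <- integer(0)
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = per_rec, size = 2,
                     endian = "little", signed = TRUE)
    if (length(block) < per_rec) {
      stop(sprintf("truncated EDF data in %s", path), call. = FALSE)
    }
    pos <- 0L
    for (i in seq_len(n_ch)) {
      raw[[i]] <- c(raw[[i]], block[(pos + 1L):(pos + spr[i])])
      pos <- pos + spr[i]
    }
  }
  fs_max <- max(spr) / rec_dur
  n_samp <- n_rec * max(spr)
  samples <- matrix(0, n_ch, n_samp)
  for (i in seq_len(n_ch)) {
    phys <- phys_min[i] + (raw[[i]] - dig_min[i]) *
      (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    if (spr[i] == max(spr)) {
      samples[i, ] <- phys
    } else {
      t_lo <- (seq_along(phys) - 1) / (spr[i] / rec_dur)
      t_hi <- (seq_len(n_samp) - 1) / fs_max
      samples[i, ] <- stats::approx(t_lo, phys, xout = t_hi, rule = 2)$y
    }
  }
  if (any(!is.finite(samples))) {
    stop(sprintf("non-finite samples decoded from %s", path), call. = FALSE)
  }
  band <- c(0.15, 536)
  bp <- regmatches(prefilter[1],
                   regexec("BP:([0-9.]+)-([0-9.]+)Hz", prefilter[1]))[[1]]
  if (length(bp) == 3) band <- as.numeric(bp[2:3])
  raw_recording(
    samples = samples,
    sample_rate_hz = fs_max,
    channels = data.frame(name = labels, label = "other", include = TRUE,
                          kind = "seeg", stringsAsFactors = FALSE),
    acq_band_hz = band
  )
}
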