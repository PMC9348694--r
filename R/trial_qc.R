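#' Trial quality-control configuration
#'
#' Two exclusion rules operate on the normalized (not yet
#' baseline-corrected) HFB time course of each trial: (A) exclude a trial
#' if its normalized power varies (max minus min) by more than
#' `prestim_range_threshold` over the pre-stimulus window; (B) exclude a
#' trial if its mean over the baseline window deviates from the mean over
#' all retained trials by more than `baseline_sd_threshold` standard
#' deviations (single pass, population SD).
#'
#' @param prestim_range_threshold Rule-A variation threshold (normalized
#'   power units).
#' @param baseline_sd_threshold Rule-B threshold in SD units.
#' @param prestim_window_s Rule-A window, half-open `[lo, hi)` seconds.
#' @param baseline_window_s Rule-B window, inclusive, seconds.
#' @param prestim_stat Rule-A variation statistic: `"sd"` (default, the
#'   standard deviation of the pre-stimulus trace) or `"range"` (max
#'   minus min). The SD reading is the default because single-window
#'   power estimates are chi-square distributed with relative SD around
#'   0.27 for any Gaussian background, so a max-minus-min reading of the
#'   0.5 threshold rejects roughly half of perfectly clean trials at any
#'   signal level, which is inconsistent with the near-complete trial
#'   retention the rule is meant to allow.
#' @return A `qc_config` list.
#' @export
qc_config <- function(prestim_range_threshold = 0.5,
                      baseline_sd_threshold = 3,
                      prestim_window_s = c(-0.2, 0),
                      baseline_window_s = c(-0.2, -0.05),
                      prestim_stat = c("sd", "range")) {
  prestim_stat <- match.arg(prestim_stat)
  check_scalar_pos(prestim_range_threshold, "prestim_range_threshold")
  check_scalar_pos(baseline_sd_threshold, "baseline_sd_threshold")
  check_range2(prestim_window_s, "prestim_window_s")
  check_range2(baseline_window_s, "baseline_window_s")
  if (prestim_window_s[2] > 0 || baseline_window_s[2] > 0) {
    stop("QC windows must lie before stimulus onset", call. = FALSE)
  }
  structure(list(
    prestim_range_threshold = prestim_range_threshold,
    baseline_sd_threshold = baseline_sd_threshold,
    prestim_window_s = prestim_window_s,
    baseline_window_s = baseline_window_s,
    prestim_stat = prestim_stat
  ), class = "qc_config")
}

check_qc_input <- function(hfb) {
  stopifnot(inherits(hfb, "hfb_response"))
  if (!hfb$normalized) {
    stop("QC expects normalized HFB power", call. = FALSE)
  }
  if (hfb$baseline_corrected) {
    stop(paste("QC must run on pre-baseline-corrected power:",
               "after window-mode correction the baseline-outlier rule is vacuous"),
         call. = FALSE)
  }
}

#' Flag trials with excessive pre-stimulus variation
#'
#' @param hfb A normalized, not baseline-corrected `hfb_response`.
#' @param cfg A [qc_config()].
#' @return Logical flags, one per trial (strict inequality; only exceeds
#'   of the threshold flag).
#' @export
flag_prestim_variation <- function(hfb, cfg = qc_config()) {
  check_qc_input(hfb)
  tol <- 1e-9
  cols <- which(hfb$times >= cfg$prestim_window_s[1] - tol &
                  hfb$times < cfg$prestim_window_s[2] - tol)
  if (length(cols) < 2) {
    stop("pre-stimulus window covers fewer than 2 time points", call. = FALSE)
  }
  seg <- hfb$timecourse[, cols, drop = FALSE]
  v <- if (cfg$prestim_stat == "range") {
    apply(seg, 1, max) - apply(seg, 1, min)
  } else {
    apply(seg, 1, stats::sd)
  }
  v > cfg$prestim_range_threshold
}

#' Flag trials with outlying baseline levels
#'
#' Computes each trial's mean normalized HFB power over the baseline
#' window and flags trials deviating from the across-trial mean by more
#' than `baseline_sd_threshold` population standard deviations. The
#' reference distribution pools all retained trials of the electrode and
#' run, in a single pass (no re-iteration after removal).
#'
#' @inheritParams flag_prestim_variation
#' @return Logical flags, one per trial (non-retained trials are never
#'   flagged).
#' @export
flag_baseline_outlier <- function(hfb, cfg = qc_config()) {
  check_qc_input(hfb)
  tol <- 1e-9
  cols <- which(hfb$times >= cfg$baseline_window_s[1] - tol &
                  hfb$times <= cfg$baseline_window_s[2] + tol)
  if (length(cols) == 0) {
    stop("baseline window lies outside the time grid", call. = FALSE)
  }
  kept <- hfb$trials$keep
  if (sum(kept) < 3) {
    stop("baseline-outlier rule needs at least 3 retained trials",
         call. = FALSE)
  }
  m <- rowMeans(hfb$timecourse[, cols, drop = FALSE])
  mu <- mean(m[kept])
  sdev <- sqrt(mean((m[kept] - mu)^2))
  flags <- abs(m - mu) > cfg$baseline_sd_threshold * sdev
  flags & kept
}

#' Apply QC flags to an HFB response
#'
#' Clears the keep flag of every flagged trial (union over rules); data
#' values are never modified. Idempotent.
#'
#' @param hfb An `hfb_response`.
#' @param ... Logical flag vectors (one element per trial).
#' @return The `hfb_response` with updated keep flags and a `qc_counts`
#'   attribute recording how many trials each rule flagged.
#' @export
apply_qc <- function(hfb, ...) {
  stopifnot(inherits(hfb, "hfb_response"))
  flag_sets <- list(...)
  n <- nrow(hfb$trials)
  combined <- rep(FALSE, n)
  counts <- integer(length(flag_sets))
  for (i in seq_along(flag_sets)) {
    f <- flag_sets[[i]]
    stopifnot(is.logical(f), length(f) == n)
    counts[i] <- sum(f & hfb$trials$keep)
    combined <- combined | f
  }
  keep_new <- hfb$trials$keep & !combined
  if (!any(keep_new)) {
    stop("QC excluded every trial", call. = FALSE)
  }
  hfb$trials$keep <- keep_new
  attr(hfb, "qc_counts") <- counts
  hfb
}
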