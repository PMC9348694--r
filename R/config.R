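#' Default analysis configuration
#'
#' All analysis constants of the pipeline with their standard values:
#' 50/100/150 Hz notch of 3 Hz total width; epochs -0.5 to +1.0 s around
#' numerosity onsets (-0.2 to +1.25 s for category stimuli); 300 ms
#' Hanning-tapered sliding-window power on a 2--122 Hz / 2 Hz grid between
#' -0.2 and +0.7 s in 10 ms steps; per-frequency normalization; baseline
#' correction over -200 to -50 ms (window mode) or at -200 ms (point
#' mode); HFB band 60--120 Hz; tuning window 100--350 ms (0--250 ms in
#' trigger-delayed mode, which couples the earlier window with point-mode
#' baseline correction because the true onset is unknown).
#'
#' @return A nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    notch = list(line_freqs = c(50, 100, 150), width_hz = 3),
    epoch = list(
      numerosity_window_s = c(-0.5, 1.0),
      # category epochs are cut from -0.5 s so the 300 ms sliding window
      # fits every centre of the standard -0.2..0.7 s grid; samples
      # before -0.2 s serve only as window support
      category_window_s = c(-0.5, 1.25),
      trigger_offset_s = 0
    ),
    spectral = list(
      window_s = 0.300,
      freq_range_hz = c(2, 122),
      freq_step_hz = 2,
      time_range_s = c(-0.2, 0.7),
      time_step_s = 0.010
    ),
    hfb = list(band_hz = c(60, 120)),
    baseline = list(mode = "window", window_s = c(-0.2, -0.05),
                    point_s = -0.2),
    tuning_window_s = c(0.100, 0.350),
    trigger_delayed_mode = FALSE,
    qc = list(
      prestim_range_threshold = 0.5,
      baseline_sd_threshold = 3,
      prestim_window_s = c(-0.2, 0),
      baseline_window_s = c(-0.2, -0.05),
      prestim_stat = "sd"
    ),
    retention = list(n_drop_small = 1, n_drop_20 = 2),
    classify = list(alpha = 0.05, min_sig_lower = 3, spearman_min = 0.8)
  ), class = "pipeline_config")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(base)) {
      stop(sprintf("unknown configuration key: %s", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]])) {
        stop(sprintf("configuration key %s must be a section", full),
             call. = FALSE)
      }
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      val <- override[[key]]
      if (is.list(val)) val <- unlist(val)
      base[[key]] <- val
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) stop(sprintf("configuration error at %s: %s", key, msg),
                  call. = FALSE)
  }
  chk(all(cfg$notch$line_freqs > 0), "notch.line_freqs", "must be positive")
  chk(cfg$notch$width_hz > 0, "notch.width_hz", "must be positive")
  chk(length(cfg$hfb$band_hz) == 2 && cfg$hfb$band_hz[1] < cfg$hfb$band_hz[2],
      "hfb.band_hz", "must be an increasing pair")
  chk(cfg$spectral$window_s > 0, "spectral.window_s", "must be positive")
  chk(diff(cfg$spectral$freq_range_hz) >= 0, "spectral.freq_range_hz",
      "must be increasing")
  chk(diff(cfg$spectral$time_range_s) >= 0, "spectral.time_range_s",
      "must be increasing")
  chk(diff(cfg$epoch$numerosity_window_s) > 0, "epoch.numerosity_window_s",
      "must be increasing")
  chk(diff(cfg$epoch$category_window_s) > 0, "epoch.category_window_s",
      "must be increasing")
  chk(cfg$baseline$mode %in% c("window", "point"), "baseline.mode",
      "must be 'window' or 'point'")
  chk(diff(cfg$tuning_window_s) > 0, "tuning_window_s", "must be increasing")
  chk(cfg$qc$prestim_range_threshold > 0, "qc.prestim_range_threshold",
      "must be positive")
  chk(cfg$qc$baseline_sd_threshold > 0, "qc.baseline_sd_threshold",
      "must be positive")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, overlays it on [default_config()] (unknown
#' keys are rejected with their full key path), validates ranges, and
#' resolves coupled switches: selecting the 0--250 ms tuning window
#' engages the trigger-delayed mode, which uses point-mode baseline
#' correction (the baseline statistic is taken at a fixed pre-trigger
#' time because the true stimulus onset is shifted by an unknown fixed
#' delay).
#'
#' @param path YAML file path (an empty file yields all defaults).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  # coupled participant-mode switch: early tuning window <=> trigger-delayed
  if (isTRUE(all.equal(as.numeric(cfg$tuning_window_s), c(0, 0.25)))) {
    cfg$trigger_delayed_mode <- TRUE
  }
  if (isTRUE(cfg$trigger_delayed_mode)) {
    cfg$baseline$mode <- "point"
    cfg$tuning_window_s <- c(0, 0.25)
  }
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}
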