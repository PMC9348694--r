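#' Stimulus timing parameters
#'
#' Bundles the timing constants of the numerosity and visual-category
#' presentation paradigms: brief dot-cloud displays (numerosities 1--7 and
#' 20) shown either in a fixed ascending/descending block sequence or in
#' semi-randomized order, and band-pass-filtered face/letter/house images
#' used as a visual-stimulation control.
#'
#' @param stim_duration_s Numerosity stimulus duration in seconds.
#' @param isi_fixed_s Fixed inter-stimulus interval of sequential-order runs.
#' @param isi_range_s Uniform ISI range of semi-randomized numerosity runs.
#' @param category_stim_duration_s Category stimulus duration in seconds.
#' @param category_isi_range_s Uniform ISI range of category runs.
#' @param presentations_per_small_block Consecutive presentations per
#'   numerosity-1--7 block in sequential runs.
#' @param presentations_per_20_block Consecutive presentations per
#'   numerosity-20 block in sequential runs.
#' @param randomized_presentations_per_numerosity Presentations per
#'   numerosity in a semi-randomized run.
#' @param category_presentations_per_level Presentations per category in a
#'   category run.
#' @param lead_in_s,lead_out_s Blank grey periods bounding each run.
#' @param n_sequence_repeats Number of times the ascending + 20 +
#'   descending + 20 block sequence is repeated within a sequential run.
#' @param numerosity_levels Integer numerosity levels presented.
#' @param category_levels Category condition labels.
#' @param oddball_rate Approximate fraction of attention-check (white-dot)
#'   presentations.
#'
#' @return An object of class `stim_params`.
#' @export
stim_params <- function(stim_duration_s = 0.250,
                        isi_fixed_s = 0.600,
                        isi_range_s = c(0.650, 0.950),
                        category_stim_duration_s = 0.500,
                        category_isi_range_s = c(1.250, 1.750),
                        presentations_per_small_block = 6L,
                        presentations_per_20_block = 12L,
                        randomized_presentations_per_numerosity = 24L,
                        category_presentations_per_level = 12L,
                        lead_in_s = 1.200,
                        lead_out_s = 1.200,
                        n_sequence_repeats = 2L,
                        numerosity_levels = c(1:7, 20L),
                        category_levels = c("face", "letter", "house"),
                        oddball_rate = 0.10) {
  check_scalar_pos(stim_duration_s, "stim_duration_s")
  check_scalar_pos(isi_fixed_s, "isi_fixed_s")
  check_scalar_pos(category_stim_duration_s, "category_stim_duration_s")
  check_range2(isi_range_s, "isi_range_s")
  check_range2(category_isi_range_s, "category_isi_range_s")
  if (any(isi_range_s <= 0)) stop_field("isi_range_s", "must be positive")
  if (any(category_isi_range_s <= 0)) {
    stop_field("category_isi_range_s", "must be positive")
  }
  for (f in c("presentations_per_small_block", "presentations_per_20_block",
              "randomized_presentations_per_numerosity",
              "category_presentations_per_level")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop_field(f, "must be a positive integer")
    }
  }
  if (!is.numeric(n_sequence_repeats) || length(n_sequence_repeats) != 1 ||
      n_sequence_repeats < 0 || n_sequence_repeats != round(n_sequence_repeats)) {
    stop_field("n_sequence_repeats", "must be a nonnegative integer")
  }
  if (!is.numeric(lead_in_s) || lead_in_s < 0) {
    stop_field("lead_in_s", "must be nonnegative")
  }
  if (!is.numeric(lead_out_s) || lead_out_s < 0) {
    stop_field("lead_out_s", "must be nonnegative")
  }
  if (!is.numeric(numerosity_levels) || length(numerosity_levels) == 0 ||
      any(numerosity_levels < 1) ||
      any(numerosity_levels != round(numerosity_levels)) ||
      anyDuplicated(numerosity_levels) > 0) {
    stop_field("numerosity_levels", "must be distinct positive integers")
  }
  if (!is.character(category_levels) || length(category_levels) == 0 ||
      anyDuplicated(category_levels) > 0) {
    stop_field("category_levels", "must be distinct labels")
  }
  if (!is.numeric(oddball_rate) || oddball_rate < 0 || oddball_rate > 1) {
    stop_field("oddball_rate", "must lie in [0, 1]")
  }
  structure(
    list(
      stim_duration_s = stim_duration_s,
      isi_fixed_s = isi_fixed_s,
      isi_range_s = isi_range_s,
      category_stim_duration_s = category_stim_duration_s,
      category_isi_range_s = category_isi_range_s,
      presentations_per_small_block = as.integer(presentations_per_small_block),
      presentations_per_20_block = as.integer(presentations_per_20_block),
      randomized_presentations_per_numerosity =
        as.integer(randomized_presentations_per_numerosity),
      category_presentations_per_level =
        as.integer(category_presentations_per_level),
      lead_in_s = lead_in_s,
      lead_out_s = lead_out_s,
      n_sequence_repeats = as.integer(n_sequence_repeats),
      numerosity_levels = as.integer(sort(numerosity_levels)),
      category_levels = category_levels,
      oddball_rate = oddball_rate
    ),
    class = "stim_params"
  )
}

new_stimulus_plan <- function(run_kind, params, events, total_duration_s,
                              seed = NA_integer_) {
  structure(
    list(
      run_kind = run_kind,
      params = params,
      events = events,
      total_duration_s = total_duration_s,
      seed = seed
    ),
    class = "stimulus_plan"
  )
}

make_events <- function(trial_type, duration, isi, lead_in, block_index,
                        within_block_index) {
  n <- length(trial_type)
  onset <- if (n == 0) numeric(0) else {
    lead_in + c(0, cumsum(duration[-n] + isi[-n]))
  }
  data.frame(
    onset = onset,
    duration = duration,
    trial_type = as.character(trial_type),
    block_index = block_index,
    within_block_index = within_block_index,
    is_oddball = rep(FALSE, n),
    keep = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

#' Build a sequential-order numerosity run plan
#'
#' One run presents numerosities 1--7 in ascending order (six consecutive
#' presentations each), a block of twelve presentations of numerosity 20,
#' the descending sweep 7--1, and another numerosity-20 block; this whole
#' sequence is repeated `n_sequence_repeats` times. Each presentation lasts
#' `stim_duration_s` and is followed by the fixed ISI; grey lead-in and
#' lead-out periods bound the run. With the default parameters the run
#' contains 216 presentations and lasts exactly 186 s.
#'
#' @param params A [stim_params()] object.
#' @return A `stimulus_plan` with `run_kind = "sequential"`.
#' @export
build_sequential_plan <- function(params = stim_params()) {
  stopifnot(inherits(params, "stim_params"))
  small <- setdiff(params$numerosity_levels, 20L)
  big <- intersect(params$numerosity_levels, 20L)
  one_rep_levels <- c(sort(small), big, rev(sort(small)), big)
  one_rep_sizes <- ifelse(one_rep_levels == 20L,
                          params$presentations_per_20_block,
                          params$presentations_per_small_block)
  levels_all <- rep(one_rep_levels, times = params$n_sequence_repeats)
  sizes_all <- rep(one_rep_sizes, times = params$n_sequence_repeats)
  trial_type <- rep(levels_all, times = sizes_all)
  n <- length(trial_type)
  block_index <- rep(seq_along(levels_all), times = sizes_all)
  within <- unlist(lapply(sizes_all, seq_len), use.names = FALSE)
  if (n == 0) {
    block_index <- integer(0)
    within <- integer(0)
  }
  duration <- rep(params$stim_duration_s, n)
  isi <- rep(params$isi_fixed_s, n)
  ev <- make_events(trial_type, duration, isi, params$lead_in_s,
                    block_index, within)
  total <- params$lead_in_s + params$lead_out_s +
    sum(duration + isi)
  new_stimulus_plan("sequential", params, ev, total)
}

#' Build a semi-randomized numerosity run plan
#'
#' Every numerosity level appears exactly
#' `randomized_presentations_per_numerosity` times in a seeded random
#' order, with each ISI drawn uniformly from `isi_range_s`. Identical seeds
#' reproduce identical plans.
#'
#' @param params A [stim_params()] object.
#' @param seed Integer seed (required; the plan is part of the experiment
#'   record and must be reproducible).
#' @param no_immediate_repeat If `TRUE`, re-draw orders until no numerosity
#'   immediately repeats itself.
#' @return A `stimulus_plan` with `run_kind = "randomized"`.
#' @export
build_randomized_plan <- function(params = stim_params(), seed,
                                  no_immediate_repeat = FALSE) {
  stopifnot(inherits(params, "stim_params"))
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is required for a randomized plan", call. = FALSE)
  }
  pool <- rep(params$numerosity_levels,
              each = params$randomized_presentations_per_numerosity)
  n <- length(pool)
  with_seed(derive_seed(seed, "randomized_plan"), {
    repeat {
      ord <- sample.int(n)
      trial_type <- pool[ord]
      if (!no_immediate_repeat || n < 2 ||
          !any(trial_type[-1] == trial_type[-n])) {
        break
      }
    }
    isi <- stats::runif(n, params$isi_range_s[1], params$isi_range_s[2])
  })
  duration <- rep(params$stim_duration_s, n)
  ev <- make_events(trial_type, duration, isi, params$lead_in_s,
                    rep(NA_integer_, n), rep(NA_integer_, n))
  total <- params$lead_in_s + params$lead_out_s + sum(duration + isi)
  new_stimulus_plan("randomized", params, ev, total, seed = as.integer(seed))
}

#' Build a visual-category control run plan
#'
#' Twelve presentations per category (faces, letters, houses) in seeded
#' random order; each presentation lasts `category_stim_duration_s` with an
#' ISI drawn uniformly from `category_isi_range_s`.
#'
#' @inheritParams build_randomized_plan
#' @return A `stimulus_plan` with `run_kind = "category"`.
#' @export
build_category_plan <- function(params = stim_params(), seed) {
  stopifnot(inherits(params, "stim_params"))
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is required for a category plan", call. = FALSE)
  }
  pool <- rep(params$category_levels,
              each = params$category_presentations_per_level)
  n <- length(pool)
  with_seed(derive_seed(seed, "category_plan"), {
    trial_type <- sample(pool)
    isi <- stats::runif(n, params$category_isi_range_s[1],
                        params$category_isi_range_s[2])
  })
  duration <- rep(params$category_stim_duration_s, n)
  ev <- make_events(trial_type, duration, isi, params$lead_in_s,
                    rep(NA_integer_, n), rep(NA_integer_, n))
  total <- params$lead_in_s + params$lead_out_s + sum(duration + isi)
  new_stimulus_plan("category", params, ev, total, seed = as.integer(seed))
}

#' Mark oddball (attention-check) presentations
#'
#' Flags a seeded random subset of presentations per numerosity level as
#' oddballs (white instead of black dots; the participant presses a
#' button). The default rule flags exactly `n_per_level` presentations per
#' level; `method = "bernoulli"` instead flags each presentation
#' independently with probability `params$oddball_rate`. Flags never alter
#' timing.
#'
#' @param plan A numerosity `stimulus_plan`.
#' @param seed Integer seed.
#' @param method `"exact"` (default) or `"bernoulli"`.
#' @param n_per_level Oddballs per level under the exact rule. Defaults to
#'   `round(rate * presentations per level)` which is 2 at the standard
#'   design (approximately 10\% of trials).
#' @return The plan with `is_oddball` flags set.
#' @export
mark_oddballs <- function(plan, seed, method = c("exact", "bernoulli"),
                          n_per_level = NULL) {
  stopifnot(inherits(plan, "stimulus_plan"))
  if (plan$run_kind == "category") {
    stop("oddballs apply to numerosity plans only", call. = FALSE)
  }
  method <- match.arg(method)
  ev <- plan$events
  ev$is_oddball <- FALSE
  rate <- plan$params$oddball_rate
  with_seed(derive_seed(seed, "oddballs"), {
    for (lev in unique(ev$trial_type)) {
      idx <- which(ev$trial_type == lev)
      if (method == "bernoulli") {
        flag <- idx[stats::runif(length(idx)) < rate]
      } else {
        k <- if (is.null(n_per_level)) {
          # canonical design: 2 oddballs per level; scales down with rate
          min(2L, as.integer(floor(rate * length(idx))))
        } else {
          as.integer(n_per_level)
        }
        k <- min(k, length(idx))
        flag <- if (k > 0) sample(idx, k) else integer(0)
      }
      ev$is_oddball[flag] <- TRUE
    }
  })
  plan$events <- ev
  plan
}

#' Clear keep flags for block-onset presentations
#'
#' Sequential-order runs present each numerosity in consecutive blocks, so
#' the first presentation of a block carries a numerosity-change onset
#' effect and is excluded from analysis. The default rule removes the first
#' presentation of each numerosity-1--7 block and the first two of each
#' numerosity-20 block, leaving 20 retained presentations per numerosity
#' 1--7 and 40 of numerosity 20 per standard run. Randomized and category
#' runs retain every presentation.
#'
#' @param events An events data frame with `block_index` and
#'   `within_block_index` columns.
#' @param run_kind `"sequential"`, `"randomized"`, or `"category"`.
#' @param n_drop_small,n_drop_20 Presentations dropped from the start of
#'   each small-numerosity / numerosity-20 block.
#' @return The events data frame with `keep` flags updated.
#' @export
retained_trial_filter <- function(events, run_kind, n_drop_small = 1L,
                                  n_drop_20 = 2L) {
  if (!run_kind %in% c("sequential", "randomized", "category")) {
    stop(sprintf("unknown run_kind '%s'", run_kind), call. = FALSE)
  }
  events$keep <- rep(TRUE, nrow(events))
  if (run_kind == "sequential" && nrow(events) > 0) {
    is20 <- events$trial_type == "20"
    drop <- ifelse(is20, events$within_block_index <= n_drop_20,
                   events$within_block_index <= n_drop_small)
    events$keep <- !drop
  }
  events
}
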