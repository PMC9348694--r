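# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make onset-to-sample conversion depend on the parity of the neighbouring
# integer; stimulus timing uses a fixed, documented rule instead.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Convert a time in seconds to a 0-based sample index at rate fs.
time_to_sample <- function(t, fs) {
  as.integer(round_half_away(t * fs))
}

# Derive a reproducible sub-seed from a root seed and a stream label.
# Keeps results independent across named streams while staying below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

# Run an expression under a local RNG state so library code never disturbs
# the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop_field(field, "must be a single positive finite number")
  }
  invisible(x)
}

check_range2 <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x)) || x[1] > x[2]) {
    stop_field(field, "must be a finite increasing pair c(lo, hi)")
  }
  invisible(x)
}
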