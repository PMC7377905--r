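# Internal validation and RNG helpers shared across modules.

# All stochastic operations take an explicit `seed`; evaluation happens in a
# temporary RNG scope so the caller's RNG stream is never disturbed.
# seed = NULL draws from the current stream (still without leaking state
# changes back when a seed *is* given).
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# Derive a child seed from a parent seed so that nested stochastic calls
# stay reproducible but decorrelated. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 1103 * k) %% 2147483629
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  assert_scalar_number(x, name)
  if (x <= 0) abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  invisible(x)
}

assert_prob <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) abort(sprintf("`%s` must lie in [0, 1].", name))
  invisible(x)
}

assert_reports <- function(r, name = "report") {
  if (!all(is.finite(r)) || !all(r == round(r)) || any(r < 1) || any(r > 6)) {
    abort(sprintf("`%s` values must be integers in 1..6.", name))
  }
  invisible(r)
}

# z-score with explicit centre/scale bookkeeping; constant columns get
# scale 1 so held-out application never divides by zero.
zscore_fit <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  list(center = m, scale = s)
}

zscore_apply <- function(x, zs) (x - zs$center) / zs$scale
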