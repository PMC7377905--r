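#' Simulate noisy sensory evidence for a random-dot-motion decision
#'
#' The generative model of a single perceptual trial is classic signal
#' detection theory: the observer receives one noisy evidence sample
#' \eqn{x \sim N(dk, \sigma)}, where \eqn{k} is motion coherence (fraction of
#' coherently moving dots), \eqn{d \in \{-1, +1\}} codes the true direction
#' (-1 left, +1 right) and \eqn{\sigma} is the level of sensory noise.
#'
#' @param k Motion coherence, a fraction in `[0, 1]`. Recycled against `d`.
#' @param d True motion direction, `-1` (left) or `+1` (right).
#' @param sigma Evidence-noise standard deviation, `> 0`.
#' @param n Number of samples per `(k, d)` pair when `k` and `d` are scalars;
#'   ignored (forced to 1 per pair) when vectors are supplied.
#' @param seed Optional integer seed; fixed seeds give bit-identical output.
#'
#' @return A tibble with columns `x` (signed evidence), `d`, `k`.
#' @examples
#' simulate_evidence(0.48, +1, sigma = 0.25, n = 5, seed = 1)
#' @export
simulate_evidence <- function(k, d, sigma, n = 1, seed = NULL) {
  assert_positive(sigma, "sigma")
  if (!all(is.finite(k)) || any(k < 0) || any(k > 1)) {
    abort("`k` must contain coherences in [0, 1].")
  }
  if (!all(d %in% c(-1, 1))) {
    abort("`d` must be -1 (left) or +1 (right).")
  }
  if (length(k) > 1L || length(d) > 1L) {
    m <- max(length(k), length(d))
    k <- rep_len(k, m)
    d <- rep_len(d, m)
  } else {
    stopifnot(n >= 1)
    k <- rep(k, n)
    d <- rep(d, n)
  }
  x <- with_rng(seed, rnorm(length(k), mean = d * k, sd = sigma))
  tibble(x = x, d = d, k = k)
}

#' Map evidence to a left/right choice
#'
#' Chooses left (`-1`) if `x < 0` and right (`+1`) if `x > 0`. The
#' measure-zero tie `x == 0` is resolved by a fair coin flip under `seed`.
#'
#' @param x Signed evidence value(s); must be finite.
#' @param seed Optional seed used only for `x == 0` ties.
#' @return Integer vector of choices in `{-1, +1}`.
#' @export
decide <- function(x, seed = NULL) {
  if (!all(is.finite(x))) abort("`x` must be finite.")
  out <- sign(x)
  ties <- out == 0
  if (any(ties)) {
    out[ties] <- with_rng(seed, sample(c(-1, 1), sum(ties), replace = TRUE))
  }
  as.integer(out)
}

#' Internal confidence from evidence strength
#'
#' Internal (private) confidence is the unsigned evidence strength
#' \eqn{z = |x|}, which is monotonically related to the probability that the
#' choice is correct given the evidence and the noise level.
#'
#' @param x Signed evidence value(s); must be finite.
#' @return Non-negative numeric vector `|x|`.
#' @export
internal_confidence <- function(x) {
  if (!all(is.finite(x))) abort("`x` must be finite.")
  abs(x)
}

#' Model-implied choice accuracy at a coherence level
#'
#' Under the evidence model \eqn{x \sim N(dk, \sigma)} with the sign rule,
#' the probability of a correct choice is \eqn{\Phi(k/\sigma)}: at zero
#' coherence performance is at chance and accuracy rises monotonically with
#' coherence and falls with noise.
#'
#' @param k Coherence(s), `>= 0`.
#' @param sigma Evidence-noise standard deviation, `> 0`.
#' @return Probability correct in `[0.5, 1)`.
#' @examples
#' predict_accuracy(0.25, sigma = 0.25) # Phi(1) ~ 0.841
#' @export
predict_accuracy <- function(k, sigma) {
  assert_positive(sigma, "sigma")
  if (!all(is.finite(k)) || any(k < 0)) abort("`k` must be >= 0.")
  pnorm(k / sigma)
}
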