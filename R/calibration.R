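#' Build a psychometric-data table
#'
#' Container for per-coherence choice accuracy from a calibration block:
#' one row per coherence level with trial and correct counts.
#'
#' @param coherence Coherence fractions in `[0, 1]`, strictly increasing.
#' @param n_trials Total trials per level, `> 0`.
#' @param n_correct Correct trials per level, `0 <= n_correct <= n_trials`.
#' @return A tibble of class `psychometric_data` with an `accuracy` column.
#' @export
psychometric_data <- function(coherence, n_trials, n_correct) {
  if (length(coherence) < 1L) abort("need at least one coherence level.")
  if (any(!is.finite(coherence)) || any(coherence < 0) || any(coherence > 1)) {
    abort("`coherence` must lie in [0, 1].")
  }
  if (is.unsorted(coherence, strictly = TRUE)) {
    abort("`coherence` must be strictly increasing.")
  }
  if (any(n_trials <= 0)) abort("`n_trials` must be > 0.")
  if (any(n_correct < 0) || any(n_correct > n_trials)) {
    abort("`n_correct` must satisfy 0 <= n_correct <= n_trials.")
  }
  out <- tibble(
    coherence = as.double(coherence),
    n_trials = as.integer(n_trials),
    n_correct = as.integer(n_correct),
    accuracy = n_correct / n_trials
  )
  class(out) <- c("psychometric_data", class(out))
  out
}

#' @rdname psychometric_data
#' @param path File path for the delimited-text (CSV) representation with
#'   columns `coherence`, `n_trials`, `n_correct`.
#' @export
read_psychometric <- function(path) {
  d <- utils::read.csv(path)
  psychometric_data(d$coherence, d$n_trials, d$n_correct)
}

#' @rdname psychometric_data
#' @param data A `psychometric_data` tibble.
#' @export
write_psychometric <- function(data, path) {
  utils::write.csv(
    data[, c("coherence", "n_trials", "n_correct")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Simulate one stimulus-calibration block
#'
#' Runs the perceptual task at the given coherences with equal numbers of
#' left and right trials and tallies accuracy per level.
#'
#' @param coherences Coherence levels to present.
#' @param trials_per_direction Trials per direction per level (block 1 uses
#'   20, block 2 uses 25).
#' @param sigma Generating evidence-noise SD of the simulated observer.
#' @param seed Optional seed.
#' @return A `psychometric_data` tibble.
#' @export
simulate_calibration_block <- function(coherences, trials_per_direction,
                                       sigma, seed = NULL) {
  assert_positive(sigma, "sigma")
  with_rng(seed, {
    n_correct <- vapply(sort(coherences), function(k) {
      ev <- simulate_evidence(
        k = rep(k, 2L * trials_per_direction),
        d = rep(c(-1, 1), each = trials_per_direction),
        sigma = sigma
      )
      sum(decide(ev$x) == ev$d)
    }, integer(1))
    psychometric_data(sort(coherences), 2L * trials_per_direction, n_correct)
  })
}

#' Fit the sensory-noise parameter to psychometric data
#'
#' Estimates \eqn{\sigma} by minimising the sum of squared errors between the
#' model-implied accuracy \eqn{\Phi(k/\sigma)} and the observed accuracy
#' across coherence levels. The 1-D objective is minimised on a dense
#' log-spaced grid followed by golden-section refinement, which avoids any
#' optimiser-tolerance ambiguity for this cheap objective.
#'
#' @param data A `psychometric_data` tibble with at least two levels.
#' @param grid_size Number of log-spaced grid points over `bounds`.
#' @param bounds Search interval for sigma.
#' @return A one-row tibble: `sigma`, `sse`, `n_levels`, `degenerate`
#'   (all accuracies at or below chance), `boundary` (solution at the edge of
#'   the search interval). Both flag conditions also raise a warning.
#' @examples
#' pd <- psychometric_data(c(.03, .06, .12, .24, .48), 40,
#'                         round(40 * predict_accuracy(c(.03, .06, .12, .24, .48), .25)))
#' fit_sigma(pd)
#' @export
fit_sigma <- function(data, grid_size = 2000, bounds = c(1e-3, 10)) {
  if (!inherits(data, "psychometric_data")) {
    data <- psychometric_data(data$coherence, data$n_trials, data$n_correct)
  }
  if (nrow(data) < 2L) {
    abort("`fit_sigma()` needs >= 2 coherence levels with nonzero trials.")
  }
  obs <- data$accuracy
  k <- data$coherence
  degenerate <- all(obs <= 0.5)
  if (degenerate) {
    warn("all observed accuracies are at or below chance; sigma is poorly identified.")
  }
  sse <- function(s) sum((pnorm(k / s) - obs)^2)
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = grid_size))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_size, i + 1L)]
  ref <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  sigma <- ref$minimum
  boundary <- i == 1L || i == grid_size
  if (boundary) {
    warn("sigma estimate lies on the search-interval boundary; treat with caution.")
  }
  tibble(
    sigma = sigma, sse = ref$objective, n_levels = nrow(data),
    degenerate = degenerate, boundary = boundary
  )
}

#' Coherence level achieving a target accuracy
#'
#' Inverts the psychometric function: the coherence at which the model
#' predicts probability correct `p` is \eqn{k = \sigma \Phi^{-1}(p)}.
#'
#' @param sigma Evidence-noise SD, `> 0`.
#' @param p Target accuracies, each strictly between 0.5 and 1.
#' @return Coherence value(s); `predict_accuracy(coherence_for_target(sigma, p), sigma)`
#'   round-trips to `p`.
#' @examples
#' coherence_for_target(0.25, c(.6, .7, .8, .9))
#' @export
coherence_for_target <- function(sigma, p) {
  assert_positive(sigma, "sigma")
  if (any(!is.finite(p)) || any(p <= 0.5) || any(p >= 1)) {
    abort("target accuracies `p` must lie strictly between 0.5 and 1.")
  }
  sigma * qnorm(p)
}

#' Two-block stimulus calibration
#'
#' Reproduces the two-block calibration procedure: block 1 presents a
#' prespecified coherence set (20 trials per direction per level), a noise
#' parameter is fitted by SSE, and block-2 coherences are chosen to hit the
#' target accuracies 60/70/80/90%. Block 2 (25 trials per direction) is then
#' refitted on its own data alone and the final coherence set and noise
#' parameter are derived from that refit.
#'
#' @param sigma_true Generating noise SD of the simulated observer.
#' @param targets Target accuracies for the main task.
#' @param block1_coherences Prespecified block-1 coherence set.
#' @param seed Optional seed (blocks use decorrelated child seeds).
#' @return A list of class `calibration`: `coherences` (final set),
#'   `sigma_block1`, `sigma_block2`, `targets`, and the two
#'   `psychometric_data` blocks.
#' @export
calibrate_coherences <- function(sigma_true,
                                 targets = c(.6, .7, .8, .9),
                                 block1_coherences = c(.03, .06, .12, .24, .48),
                                 seed = NULL) {
  block1 <- simulate_calibration_block(block1_coherences, 20L, sigma_true,
                                       seed = child_seed(seed, 1L))
  fit1 <- fit_sigma(block1)
  k2 <- coherence_for_target(fit1$sigma, sort(targets))
  block2 <- simulate_calibration_block(k2, 25L, sigma_true,
                                       seed = child_seed(seed, 2L))
  fit2 <- fit_sigma(block2)
  structure(
    list(
      coherences = coherence_for_target(fit2$sigma, sort(targets)),
      sigma_block1 = fit1$sigma,
      sigma_block2 = fit2$sigma,
      targets = sort(targets),
      block1 = block1,
      block2 = block2
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("Two-block stimulus calibration\n")
  cat(sprintf("  sigma (block 1): %.4f\n", x$sigma_block1))
  cat(sprintf("  sigma (block 2): %.4f\n", x$sigma_block2))
  cat("  final coherences:",
      paste(sprintf("%.3f", x$coherences), collapse = ", "), "\n")
  cat("  target accuracies:",
      paste(sprintf("%.0f%%", 100 * x$targets), collapse = ", "), "\n")
  invisible(x)
}
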