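#' Define a simulated partner profile
#'
#' A partner is an SDT agent whose choice accuracy matches the subject's at
#' every coherence level but whose confidence-report distribution over the
#' 1..6 scale is imposed exactly, so that partners differ only in how they
#' report confidence, not in how well they choose.
#'
#' @param partner_id Label, one of `"low"`, `"medium-low"`, `"medium-high"`,
#'   `"high"` (other labels are allowed for custom agents).
#' @param report_probs Probabilities over reports 1..6 (non-negative, summing
#'   to 1). Per-session target counts are derived by largest-remainder
#'   rounding so they always sum to the session length.
#' @param tolerance Maximum absolute deviation allowed between a session's
#'   realized per-coherence accuracy and its target accuracy (fraction;
#'   default 0.01, i.e. within 1%).
#' @param target_accuracy Optional named vector of per-coherence target
#'   accuracies; by default targets are the model-implied accuracies
#'   `predict_accuracy(k, sigma)` at simulation time.
#' @return A list of class `partner_profile`.
#' @export
partner_profile <- function(partner_id, report_probs, tolerance = 0.01,
                            target_accuracy = NULL) {
  if (length(report_probs) != 6L || any(report_probs < 0)) {
    abort("`report_probs` must be 6 non-negative values.")
  }
  if (abs(sum(report_probs) - 1) > 1e-8) {
    abort("`report_probs` must sum to 1.")
  }
  assert_positive(tolerance, "tolerance")
  structure(
    list(
      partner_id = partner_id,
      report_probs = report_probs / sum(report_probs),
      tolerance = tolerance,
      target_accuracy = target_accuracy
    ),
    class = "partner_profile"
  )
}

#' Default partner set: low to high mean confidence
#'
#' The published partner confidence distributions are not tabulated, so the
#' defaults are surrogate values: four discretised Gaussians over the 1..6
#' scale with matched spread and means near 2, 3, 4 and 5, giving strictly
#' ordered mean confidence (low < medium-low < medium-high < high) with
#' identical target choice accuracy.
#'
#' @param spread SD of the latent Gaussian before discretisation.
#' @param tolerance Accuracy tolerance passed to each profile.
#' @return Named list of four `partner_profile` objects.
#' @export
default_partner_profiles <- function(spread = 1.0, tolerance = 0.01) {
  ids <- c("low", "medium-low", "medium-high", "high")
  mus <- c(2, 3, 4, 5)
  out <- lapply(seq_along(ids), function(i) {
    w <- dnorm(1:6, mus[i], spread)
    partner_profile(ids[i], w / sum(w), tolerance = tolerance)
  })
  names(out) <- ids
  out
}

#' Target report counts for a session length
#'
#' Largest-remainder rounding of `report_probs * n`: counts are non-negative
#' integers that always sum to `n`.
#'
#' @param profile A `partner_profile`.
#' @param n Session length in trials.
#' @return Integer vector of length 6.
#' @export
report_counts <- function(profile, n) {
  stopifnot(inherits(profile, "partner_profile"), n >= 1)
  largest_remainder(profile$report_probs, n)
}

#' Set confidence thresholds to achieve an exact report distribution
#'
#' Given the session's internal-confidence values `z` and a target count for
#' each report 1..6, places five ascending thresholds in z-space such that
#' applying them reproduces the target histogram exactly. Assignment is by
#' rank of `z` (ties broken deterministically by trial index), which
#' guarantees exact counts even with tied `z`.
#'
#' @param z Unsigned internal-confidence values, one per trial.
#' @param target_counts Six counts summing to `length(z)`.
#' @return A list: `thresholds` (5 non-decreasing z-space cuts) and `report`
#'   (the exact rank-based report per trial, aligned with `z`).
#' @export
thresholds_from_distribution <- function(z, target_counts) {
  if (!all(is.finite(z))) abort("`z` must be finite.")
  if (length(target_counts) != 6L || any(target_counts < 0) ||
      any(target_counts != round(target_counts))) {
    abort("`target_counts` must be 6 non-negative integers.")
  }
  n <- length(z)
  if (sum(target_counts) != n) {
    abort("`target_counts` must sum to length(z).")
  }
  ord <- order(z) # stable: ties keep trial-index order
  report <- integer(n)
  report[ord] <- rep.int(1:6, target_counts)
  zs <- z[ord]
  cuts <- cumsum(target_counts)[1:5]
  thresholds <- vapply(cuts, function(cu) {
    if (cu == 0) zs[1] - 1 else if (cu == n) zs[n] + 1
    else (zs[cu] + zs[cu + 1]) / 2
  }, numeric(1))
  list(thresholds = cummax(thresholds), report = report)
}

#' Simulate a partner's session under an accuracy constraint
#'
#' Draws evidence for the whole session from the SDT model and accepts the
#' draw only if the partner's realized choice accuracy is within
#' `profile$tolerance` of the target accuracy at every coherence level
#' (whole-session rejection sampling, so the generative law of the evidence
#' is preserved). Confidence reports are then imposed deterministically by
#' rank-based thresholding, so the report histogram matches the profile's
#' target counts exactly regardless of the rejection step.
#'
#' @param stimuli Tibble/data frame with columns `coherence` and `direction`
#'   (`-1`/`+1`), balanced across coherence levels.
#' @param sigma Evidence-noise SD used for the partner (the subject's
#'   calibrated value).
#' @param profile A `partner_profile`.
#' @param max_attempts Rejection-sampling budget (default 10000).
#' @param seed Optional seed; fixed seeds reproduce the session exactly.
#' @return A list of class `partner_session`: `trials` (tibble with
#'   `trial`, `coherence`, `direction`, `choice`, `correct`, `report`),
#'   `realized_accuracy` (per-coherence tibble with targets and deviations),
#'   `thresholds`, `attempts`, `partner_id`.
#' @export
simulate_partner_session <- function(stimuli, sigma, profile,
                                     max_attempts = 10000, seed = NULL) {
  stopifnot(inherits(profile, "partner_profile"), max_attempts >= 1)
  assert_positive(sigma, "sigma")
  stimuli <- as_tibble(stimuli)
  if (!all(c("coherence", "direction") %in% names(stimuli))) {
    abort("`stimuli` needs columns `coherence` and `direction`.")
  }
  if (!all(stimuli$direction %in% c(-1, 1))) abort("`direction` must be -1/+1.")
  n <- nrow(stimuli)
  kf <- factor(stimuli$coherence)
  if (length(unique(table(kf))) != 1L) {
    abort("`stimuli` must be balanced across coherence levels.")
  }
  klev <- as.numeric(levels(kf))
  target <- profile$target_accuracy
  if (is.null(target)) {
    target <- predict_accuracy(klev, sigma)
  } else {
    target <- unname(target[as.character(klev)])
    if (any(is.na(target))) abort("`target_accuracy` missing a coherence level.")
  }
  tol <- profile$tolerance
  kidx <- as.integer(kf)
  n_per <- tabulate(kidx)

  res <- with_rng(seed, {
    attempts <- 0L
    accepted <- NULL
    viol_count <- numeric(length(klev))
    chunk <- min(max_attempts, 256L)
    while (attempts < max_attempts && is.null(accepted)) {
      m <- min(chunk, max_attempts - attempts)
      X <- matrix(rnorm(n * m, mean = stimuli$direction * stimuli$coherence,
                        sd = sigma), nrow = n)
      corr <- (X > 0) == (stimuli$direction > 0)
      zeros <- X == 0 # measure-zero choice tie: fair coin
      if (any(zeros)) corr[zeros] <- runif(sum(zeros)) < 0.5
      dev <- abs(rowsum(corr + 0, kidx) / n_per - target) # levels x m
      ok <- colSums(dev <= tol + 1e-12) == length(klev)
      j <- which(ok)[1]
      if (!is.na(j)) {
        if (j > 1L) viol_count <- viol_count +
            rowSums(dev[, seq_len(j - 1L), drop = FALSE] > tol + 1e-12)
        accepted <- list(x = X[, j], correct = corr[, j],
                         attempts = attempts + j,
                         acc = rowsum(corr[, j] + 0, kidx)[, 1] / n_per)
      } else {
        viol_count <- viol_count + rowSums(dev > tol + 1e-12)
      }
      attempts <- attempts + m
    }
    if (is.null(accepted)) {
      worst <- klev[which.max(viol_count)]
      abort(sprintf(
        "accuracy constraint not met in %d attempts; most-violated coherence level: %.3f",
        max_attempts, worst))
    }
    accepted
  })

  choice <- ifelse(res$correct, stimuli$direction, -stimuli$direction)
  z <- internal_confidence(res$x)
  thr <- thresholds_from_distribution(z, report_counts(profile, n))
  realized <- tibble(
    coherence = klev,
    n_trials = n_per,
    target_accuracy = target,
    realized_accuracy = res$acc,
    deviation = abs(res$acc - target)
  )
  structure(
    list(
      trials = tibble(
        trial = seq_len(n),
        coherence = stimuli$coherence,
        direction = stimuli$direction,
        choice = as.integer(choice),
        correct = res$correct,
        report = thr$report
      ),
      realized_accuracy = realized,
      thresholds = thr$thresholds,
      attempts = res$attempts,
      partner_id = profile$partner_id
    ),
    class = "partner_session"
  )
}

#' Mean confidence of a partner session
#'
#' @param session A `partner_session` (or any tibble with a `report` column).
#' @return Arithmetic mean report, in `[1, 6]`.
#' @export
mean_confidence <- function(session) {
  r <- if (inherits(session, "partner_session")) session$trials$report
       else session$report
  if (length(r) == 0) abort("empty session.")
  assert_reports(r)
  mean(r)
}

#' @export
print.partner_session <- function(x, ...) {
  cat(sprintf("Partner session (%s): %d trials, %d attempt(s)\n",
              x$partner_id, nrow(x$trials), x$attempts))
  cat(sprintf("  mean confidence %.2f; max accuracy deviation %.3f\n",
              mean(x$trials$report), max(x$realized_accuracy$deviation)))
  invisible(x)
}
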