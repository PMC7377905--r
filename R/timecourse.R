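#' Exclude reaction-time outlier trials
#'
#' Removes trials whose choice reaction time lies more than
#' `threshold_sd` standard deviations from the grand mean RT (default 2.5
#' SD, computed over the supplied trials). When all RTs are identical the
#' SD is zero and nothing is excluded.
#'
#' @param trials Tibble with a positive `rt` column.
#' @param threshold_sd Exclusion threshold in SD units.
#' @return The retained trials, with the excluded rows in attribute
#'   `"excluded"`.
#' @export
filter_rt_outliers <- function(trials, threshold_sd = 2.5) {
  trials <- as_tibble(trials)
  if (!"rt" %in% names(trials)) abort("`trials` needs an `rt` column.")
  if (any(trials$rt <= 0)) abort("`rt` must be positive.")
  m <- mean(trials$rt)
  s <- stats::sd(trials$rt)
  keep <- if (!is.finite(s) || s == 0) rep(TRUE, nrow(trials))
          else abs(trials$rt - m) <= threshold_sd * s
  if (!any(keep)) abort("all trials excluded by the RT criterion.")
  out <- trials[keep, ]
  attr(out, "excluded") <- trials[!keep, ]
  out
}

#' Discrete-cosine high-pass filter
#'
#' Removes slow scanner drifts by regressing out a discrete-cosine basis
#' with the given cutoff period (default 128 s) from a uniformly sampled
#' signal, the standard fMRI high-pass convention.
#'
#' @param value Sampled signal.
#' @param time Sample times (s), uniformly spaced.
#' @param cutoff_s Cutoff period in seconds.
#' @return Filtered signal (mean removed together with the drift terms).
#' @export
dct_highpass <- function(value, time, cutoff_s = 128) {
  n <- length(value)
  stopifnot(length(time) == n, n > 2)
  dur <- time[n] - time[1]
  k_max <- floor(2 * dur / cutoff_s + 1)
  tt <- seq_len(n) - 1
  basis <- vapply(seq_len(k_max), function(k)
    cos(pi * (2 * tt + 1) * k / (2 * n)), numeric(n))
  fit <- lm.fit(cbind(1, basis), value)
  fit$residuals
}

#' Extract trial-locked epochs from an ROI time course
#'
#' Interpolates a (drift-filtered) ROI signal onto a fine grid time-locked
#' to each event: a 12 s window from 2 s before to 10 s after onset,
#' oversampled to a 0.144 s resolution by linear interpolation. Trials whose
#' window extends past the recording are dropped with a log entry.
#'
#' @param timecourse Tibble with columns `time` (s) and `value`.
#' @param onsets Event onset times (s).
#' @param window Window relative to onset, `c(start, end)` in seconds.
#' @param dt Sample spacing of the epoch grid (s).
#' @param highpass_s Cutoff of the discrete-cosine drift filter applied
#'   before epoching; `NULL` to skip.
#' @return A list of class `epoch_matrix`: `epochs` (trials x timepoints),
#'   `time` (grid relative to onset), `onsets` (retained), `dropped`
#'   (indices of dropped events).
#' @export
extract_epochs <- function(timecourse, onsets, window = c(-2, 10),
                           dt = 0.144, highpass_s = 128) {
  timecourse <- as_tibble(timecourse)
  stopifnot(all(c("time", "value") %in% names(timecourse)), dt > 0)
  value <- timecourse$value
  if (!is.null(highpass_s)) {
    value <- dct_highpass(value, timecourse$time, highpass_s)
  }
  grid <- seq(window[1], window[2], by = dt)
  lo <- min(timecourse$time); hi <- max(timecourse$time)
  ok <- onsets + window[1] >= lo & onsets + window[2] <= hi
  dropped <- which(!ok)
  if (length(dropped)) {
    warn(sprintf("%d event(s) extend past the recording and were dropped.",
                 length(dropped)))
  }
  kept <- onsets[ok]
  if (length(kept) == 0L) abort("no events lie fully within the recording.")
  ep <- t(vapply(kept, function(o)
    approx(timecourse$time, value, xout = o + grid)$y, numeric(length(grid))))
  structure(list(epochs = ep, time = grid, onsets = kept, dropped = dropped),
            class = "epoch_matrix")
}

# z-score columns of a predictor table; constant columns left centred
zscore_cols <- function(df) {
  as.matrix(as.data.frame(lapply(df, function(x) {
    zs <- zscore_fit(as.numeric(x))
    zscore_apply(as.numeric(x), zs)
  })))
}

#' Per-timepoint encoding regression
#'
#' Fits an ordinary least-squares regression of trial activity on the
#' (z-scored) trial covariates separately at every timepoint of the epoch
#' grid and concatenates the beta weights into one time course per
#' predictor.
#'
#' @param epochs An `epoch_matrix`.
#' @param predictors Tibble of per-trial covariates, rows aligned with the
#'   epoch rows; z-scored internally.
#' @return Tibble with columns `time`, `term`, `beta` (and a `rank_deficient`
#'   flag per timepoint).
#' @export
pointwise_glm <- function(epochs, predictors) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  predictors <- as_tibble(predictors)
  n <- nrow(epochs$epochs)
  if (nrow(predictors) != n) abort("predictor rows must align with epochs.")
  if (n < ncol(predictors) + 2L) abort("too few trials for the model.")
  X <- cbind(`(Intercept)` = 1, zscore_cols(predictors))
  full_rank <- ncol(X)
  purrr::map_dfr(seq_along(epochs$time), function(ti) {
    fit <- lm.fit(X, epochs$epochs[, ti])
    b <- fit$coefficients[-1]
    tibble(time = epochs$time[ti], term = names(b), beta = unname(b),
           rank_deficient = fit$rank < full_rank)
  })
}

#' Psychophysiological-interaction regression
#'
#' Predicts a target region's trial-locked activity from the interaction
#' between a seed region's activity and trial covariates (private
#' confidence, reported confidence, and their product), while controlling
#' for the main effect of every term: at each timepoint the model is
#' `target ~ seed + private + reported + private:reported + seed:private +
#' seed:reported + seed:private:reported`. The three seed-interaction beta
#' traces quantify how seed-target coupling varies with confidence.
#'
#' @param target_epochs,seed_epochs `epoch_matrix` objects with identical
#'   trial sets and time grids.
#' @param private,reported Per-trial covariates aligned with the epochs.
#' @return Tibble `time` x `term` x `beta` for all seven terms; the
#'   interaction traces carry terms `"seed:private"`, `"seed:reported"`,
#'   `"seed:private:reported"`.
#' @export
ppi_glm <- function(target_epochs, seed_epochs, private, reported) {
  stopifnot(inherits(target_epochs, "epoch_matrix"),
            inherits(seed_epochs, "epoch_matrix"))
  if (!isTRUE(all.equal(target_epochs$time, seed_epochs$time)) ||
      nrow(target_epochs$epochs) != nrow(seed_epochs$epochs)) {
    abort("seed and target epochs must be aligned trial-for-trial.")
  }
  n <- nrow(target_epochs$epochs)
  if (length(private) != n || length(reported) != n) {
    abort("covariates must align with the epochs.")
  }
  pz <- zscore_apply(private, zscore_fit(private))
  rz <- zscore_apply(reported, zscore_fit(reported))
  purrr::map_dfr(seq_along(target_epochs$time), function(ti) {
    s <- seed_epochs$epochs[, ti]
    sz <- zscore_apply(s, zscore_fit(s))
    X <- cbind(`(Intercept)` = 1, seed = sz, private = pz, reported = rz,
               `private:reported` = pz * rz,
               `seed:private` = sz * pz, `seed:reported` = sz * rz,
               `seed:private:reported` = sz * pz * rz)
    fit <- lm.fit(X, target_epochs$epochs[, ti])
    b <- fit$coefficients[-1]
    tibble(time = target_epochs$time[ti], term = names(b), beta = unname(b))
  })
}

#' Group-level test of beta traces across subjects
#'
#' One-sample t-test of per-subject beta weights against zero at each
#' timepoint, with a significance mask at the given alpha (per-timepoint,
#' uncorrected — no correction across timepoints is applied).
#'
#' @param traces Tibble with columns `subject`, `time`, `term`, `beta`
#'   (e.g. row-bound outputs of [pointwise_glm()] or [ppi_glm()]).
#' @param alpha Per-timepoint significance level.
#' @return Tibble with `time`, `term`, `mean_beta`, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
group_timepoint_test <- function(traces, alpha = 0.05) {
  traces <- as_tibble(traces)
  need <- c("subject", "time", "term", "beta")
  if (!all(need %in% names(traces))) {
    abort("`traces` needs columns subject, time, term, beta.")
  }
  out <- dplyr::summarise(
    dplyr::group_by(traces, .data$time, .data$term),
    mean_beta = mean(.data$beta),
    df = dplyr::n() - 1,
    t = if (stats::sd(.data$beta) == 0) {
          ifelse(mean(.data$beta) == 0, 0, sign(mean(.data$beta)) * Inf)
        } else mean(.data$beta) / (stats::sd(.data$beta) / sqrt(dplyr::n())),
    .groups = "drop"
  )
  out$p_value <- 2 * stats::pt(-abs(out$t), out$df)
  out$significant <- out$p_value < alpha
  out
}

#' Average beta traces over a time window
#'
#' Convenience for window-based group tests (e.g. the 6-8 s post-onset
#' window used to summarise late coupling effects).
#'
#' @param traces Tibble with `time`, `term`, `beta` and optional grouping
#'   columns (e.g. `subject`).
#' @param from,to Window bounds in seconds (inclusive).
#' @return The input collapsed over `time` within the window (mean beta).
#' @export
window_mean <- function(traces, from = 6, to = 8) {
  traces <- as_tibble(traces)
  sel <- traces[traces$time >= from & traces$time <= to, ]
  grp <- intersect(c("subject", "term"), names(sel))
  dplyr::summarise(dplyr::group_by(sel, dplyr::across(dplyr::all_of(grp))),
                   beta = mean(.data$beta), .groups = "drop")
}
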