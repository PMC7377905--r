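#' Apply the group-decision rule
#'
#' On every trial the individual decision made with higher reported
#' confidence is selected as the group decision. Equal reports are resolved
#' by a fair random selection under `seed` (the task never discloses a tie
#' rule, so an unbiased coin is used).
#'
#' Inputs are vectorised over trials.
#'
#' @param subject_choice,partner_choice Choices in `{-1, +1}`.
#' @param subject_report,partner_report Confidence reports in 1..6.
#' @param seed Optional seed used only for ties.
#' @return A tibble with `group_choice` and `selected`
#'   (`"subject"`/`"partner"`).
#' @export
group_decision <- function(subject_choice, subject_report,
                           partner_choice, partner_report, seed = NULL) {
  assert_reports(subject_report, "subject_report")
  assert_reports(partner_report, "partner_report")
  if (!all(subject_choice %in% c(-1, 1)) || !all(partner_choice %in% c(-1, 1))) {
    abort("choices must be -1/+1.")
  }
  n <- length(subject_report)
  sel <- ifelse(subject_report > partner_report, "subject",
                ifelse(subject_report < partner_report, "partner", NA))
  ties <- is.na(sel)
  if (any(ties)) {
    sel[ties] <- with_rng(seed,
      sample(c("subject", "partner"), sum(ties), replace = TRUE))
  }
  tibble(
    group_choice = as.integer(
      ifelse(sel == "subject", subject_choice, partner_choice)),
    selected = sel
  )
}

#' Probability that the subject's decision is selected
#'
#' Given the subject's report `r` and the partner's confidence-report
#' distribution, the probability of the subject's decision becoming the
#' group decision is \eqn{P(r_p < r) + \tfrac{1}{2} P(r_p = r)}, the half
#' weight matching the fair random tie-break of [group_decision()].
#'
#' @param report Subject report(s) in 1..6 (vectorised).
#' @param partner_dist Probability vector over partner reports 1..6.
#' @return Selection probabilities in `[0, 1]`, monotone non-decreasing in
#'   `report`.
#' @examples
#' selection_probability(3, rep(1 / 6, 6)) # 5/12
#' @export
selection_probability <- function(report, partner_dist) {
  assert_reports(report, "report")
  if (length(partner_dist) != 6L || any(partner_dist < 0) ||
      abs(sum(partner_dist) - 1) > 1e-8) {
    abort("`partner_dist` must be 6 non-negative probabilities summing to 1.")
  }
  cum <- c(0, cumsum(partner_dist))
  cum[report] + 0.5 * partner_dist[report]
}

# Discretised-Gaussian report distribution used as the parametric report
# policy family (partners and the strategy sweep share it).
report_distribution <- function(mean, spread = 1.0) {
  if (mean < 1 || mean > 6) abort("report-policy mean must lie in [1, 6].")
  w <- dnorm(1:6, mean, spread)
  w / sum(w)
}

#' Expected group accuracy for a subject report policy
#'
#' Monte-Carlo estimate of the probability that the group decision is
#' correct when a subject adopting a confidence policy with the given mean
#' report plays with a partner. Both agents are SDT observers with the same
#' noise level viewing the same stimulus (independent evidence samples);
#' reports are imposed by rank-based thresholding of each agent's internal
#' confidence so the report histograms match the policies exactly, and the
#' group decision follows [group_decision()].
#'
#' Because the selected decision is the higher-confidence one, group
#' accuracy is maximised when the subject's mean confidence matches the
#' partner's: reporting systematically higher (lower) than the partner makes
#' the group over- (under-) weight the subject's evidence.
#'
#' @param subject_mean_conf Target mean report of the subject policy,
#'   in `[1, 6]`.
#' @param partner A `partner_profile`.
#' @param sigma Evidence-noise SD for both agents.
#' @param coherences Calibrated coherence levels (default: targets
#'   60/70/80/90% at this sigma).
#' @param n_sim Simulated trials (balanced over coherences).
#' @param spread SD of the discretised-Gaussian subject policy.
#' @param seed Optional seed.
#' @return Scalar Monte-Carlo estimate of P(group decision correct).
#' @export
expected_group_accuracy <- function(subject_mean_conf, partner, sigma,
                                    coherences = NULL, n_sim = 10000,
                                    spread = 1.0, seed = NULL) {
  stopifnot(inherits(partner, "partner_profile"))
  assert_positive(sigma, "sigma")
  subj_dist <- report_distribution(subject_mean_conf, spread)
  if (is.null(coherences)) {
    coherences <- coherence_for_target(sigma, c(.6, .7, .8, .9))
  }
  n_sim <- as.integer(n_sim / length(coherences)) * length(coherences)
  with_rng(seed, {
    k <- rep(coherences, length.out = n_sim)
    d <- sample(c(-1L, 1L), n_sim, replace = TRUE)
    xs <- rnorm(n_sim, d * k, sigma)
    xp <- rnorm(n_sim, d * k, sigma)
    counts_s <- largest_remainder(subj_dist, n_sim)
    counts_p <- largest_remainder(partner$report_probs, n_sim)
    rs <- thresholds_from_distribution(abs(xs), counts_s)$report
    rp <- thresholds_from_distribution(abs(xp), counts_p)$report
    gd <- group_decision(decide(xs), rs, decide(xp), rp)
    mean(gd$group_choice == d)
  })
}

largest_remainder <- function(probs, n) {
  raw <- probs * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Sweep subject mean confidence against a partner
#'
#' Runs [expected_group_accuracy()] over a grid of subject mean reports,
#' reproducing the strategy experiment in which group accuracy peaks where
#' the subject matches the partner's mean confidence. All grid points share
#' one set of evidence draws (common random numbers), so differences along
#' the grid reflect the report policy alone rather than Monte-Carlo noise —
#' without this the location of the near-flat maximum is unstable.
#'
#' @param means Grid of subject mean reports (default 1.5 to 5.5 by 0.25).
#' @param partner A `partner_profile`.
#' @inheritParams expected_group_accuracy
#' @return A tibble with `subject_mean`, `group_accuracy` and the partner's
#'   mean confidence in attribute `"partner_mean"`.
#' @export
sweep_group_accuracy <- function(partner, sigma,
                                 means = seq(1.5, 5.5, by = 0.25),
                                 coherences = NULL, n_sim = 10000,
                                 spread = 1.0, seed = NULL) {
  crn_seed <- child_seed(seed, 1L) %||% sample.int(2^30, 1)
  acc <- purrr::map_dbl(seq_along(means), function(i) {
    expected_group_accuracy(means[i], partner, sigma,
                            coherences = coherences, n_sim = n_sim,
                            spread = spread, seed = crn_seed)
  })
  out <- tibble(subject_mean = means, group_accuracy = acc)
  attr(out, "partner_mean") <- sum(1:6 * partner$report_probs)
  out
}

#' Running selection statistics shown to the subject
#'
#' Subjects are informed at a fixed cadence how often their individual
#' decision has been selected as the group decision for each partner; the
#' statistic is the running mean of per-trial selection probabilities (or
#' realised selection flags) over that partner's signalled trials, reset at
#' the start of every run.
#'
#' @param trials Tibble with columns `context`, and either `selection_prob`
#'   or a logical `selected` flag; an optional `run` column scopes the reset
#'   (default: one run).
#' @param every Update cadence in trials (40 in the prescan session, 20 in
#'   the scan session).
#' @return A tibble with one row per (run, update point, partner):
#'   `run`, `trial` (position within run), `context`, `n_trials`
#'   (signalled trials of that partner so far in the run) and
#'   `selection_rate`.
#' @export
update_statistics <- function(trials, every) {
  if (!is.numeric(every) || length(every) != 1L || every <= 0) {
    abort("`every` must be a positive number of trials.")
  }
  trials <- as_tibble(trials)
  if (!"run" %in% names(trials)) trials$run <- 1L
  val <- if ("selection_prob" %in% names(trials)) trials$selection_prob
         else if ("selected" %in% names(trials)) as.numeric(trials$selected)
         else abort("`trials` needs a `selection_prob` or `selected` column.")
  trials$.val <- val
  purrr::map_dfr(split(trials, trials$run), function(tr) {
    n <- nrow(tr)
    pts <- seq(every, n, by = every)
    purrr::map_dfr(pts, function(p) {
      upto <- tr[seq_len(p), ]
      upto <- upto[!is.na(upto$context) & upto$context != "hidden", ]
      dplyr::summarise(
        dplyr::group_by(upto, .data$context),
        n_trials = dplyr::n(),
        selection_rate = mean(.data$.val),
        .groups = "drop"
      ) |>
        dplyr::mutate(run = tr$run[1], trial = p, .before = 1)
    })
  })
}
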