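#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma HRF: a response gamma (shape 6, unit rate; mode
#' near 5 s) minus an undershoot gamma (shape 16) scaled by 1/6, normalised
#' to unit peak.
#'
#' @param t Times in seconds (values at `t < 0` are 0).
#' @param peak,undershoot Gamma shape parameters of the two components
#'   (unit time scale; the response mode is `peak - 1` seconds).
#' @param ratio Undershoot amplitude relative to the response.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, shape = peak, rate = 1) -
                ratio * stats::dgamma(t, shape = undershoot, rate = 1))
  h / max(stats::dgamma(seq(0, 30, by = 0.01), shape = peak, rate = 1))
}

# CDF of internal confidence z = |x| for x ~ N(±k, sigma), averaged over a
# balanced set of coherences: used to place subject report thresholds at
# deterministic quantiles.
z_quantiles <- function(p, coherences, sigma) {
  Fz <- function(z) mean(pnorm((z - coherences) / sigma) -
                           pnorm((-z - coherences) / sigma))
  vapply(p, function(pp) {
    stats::uniroot(function(z) Fz(z) - pp, c(0, 50 * sigma),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Specify a synthetic subject
#'
#' Generative parameters of one simulated subject: sensory noise, a fixed
#' report policy (five ascending thresholds on internal confidence
#' `z = |x|`), additive context-dependent report shifts, and a reaction-time
#' model in which RT decreases with evidence strength
#' (`rt = base + slope / (|x| + eps) * lognormal noise`), so that log RT
#' carries confidence information beyond coherence.
#'
#' @param sigma Evidence-noise SD.
#' @param context_shifts Named additive report shifts (report units) for the
#'   four partner contexts; the hidden condition always has shift 0.
#' @param rt_params List with `base` (s), `slope`, `eps`, `sdlog`.
#' @param report_thresholds Five ascending z-space thresholds, or `NULL` to
#'   place them at the quantiles of the model-implied `|x|` distribution
#'   that give a bell-shaped baseline report distribution centred mid-scale
#'   (requires `coherences`).
#' @param coherences Calibrated coherence set used for the default
#'   thresholds.
#' @param baseline_mean,baseline_spread Mean/spread of the discretised
#'   Gaussian targeted by the default thresholds.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(sigma = 0.25,
                         context_shifts = c("low" = -1, "medium-low" = -0.4,
                                            "medium-high" = 0.4, "high" = 1),
                         rt_params = list(base = 0.3, slope = 0.2,
                                          eps = 0.1, sdlog = 0.3),
                         report_thresholds = NULL,
                         coherences = NULL,
                         baseline_mean = 3.5, baseline_spread = 1.3) {
  assert_positive(sigma, "sigma")
  if (!all(PARTNER_LEVELS %in% names(context_shifts))) {
    abort("`context_shifts` must name all four partner contexts.")
  }
  with(rt_params, {
    if (base <= 0 || slope < 0 || eps <= 0 || sdlog < 0) {
      abort("`rt_params` must yield positive RTs (base, eps > 0; slope, sdlog >= 0).")
    }
  })
  if (is.null(report_thresholds)) {
    if (is.null(coherences)) {
      coherences <- coherence_for_target(sigma, c(.6, .7, .8, .9))
    }
    probs <- report_distribution(baseline_mean, baseline_spread)
    report_thresholds <- z_quantiles(cumsum(probs)[1:5], coherences, sigma)
  }
  if (length(report_thresholds) != 5L ||
      is.unsorted(report_thresholds, strictly = TRUE)) {
    abort("`report_thresholds` must be 5 strictly ascending values.")
  }
  structure(
    list(sigma = sigma,
         context_shifts = c(context_shifts[PARTNER_LEVELS], hidden = 0),
         rt_params = rt_params,
         report_thresholds = report_thresholds),
    class = "subject_spec"
  )
}

# one behavioural pass of the subject over a design: evidence, choice, RT,
# context-shifted report; ground-truth columns (x, z, base_report) retained
subject_pass <- function(design, spec) {
  n <- nrow(design)
  x <- rnorm(n, design$direction * design$coherence, spec$sigma)
  choice <- decide(x)
  z <- abs(x)
  rp <- spec$rt_params
  rt <- rp$base + rp$slope / (z + rp$eps) * rlnorm(n, 0, rp$sdlog)
  base_report <- 1L + rowSums(outer(z, spec$report_thresholds, ">"))
  ctx <- as.character(design$context)
  shift <- ifelse(is.na(ctx), 0, spec$context_shifts[ctx])
  # stochastic rounding: a fractional shift moves the mean report by
  # exactly that amount (in expectation, before boundary clipping)
  shifted <- base_report + shift
  report <- floor(shifted) + rbinom(n, 1L, shifted - floor(shifted))
  report <- pmin(6L, pmax(1L, as.integer(report)))
  tibble::add_column(
    design,
    x = x, z = z, choice = choice, correct = choice == design$direction,
    rt = rt, base_report = as.integer(base_report), report = report,
    marker_start = sample(1:6, n, replace = TRUE)
  )
}

#' Generate a full synthetic study for one subject
#'
#' Builds the designs for the behavioural phases and the scan runs, plays
#' the subject (an SDT observer with a fixed threshold report policy plus
#' additive context shifts, stochastically rounded to the report grid and
#' clipped to the 1..6 scale) through them, and
#' fills in the social layer: in the block-wise and interleaved phases the
#' partners' responses are simulated under the accuracy constraint and the
#' group decision is played out; in the hidden-context phase and scan runs
#' the per-trial selection probability is computed from the partner's
#' report distribution instead, as in the task.
#'
#' @param spec A `subject_spec`.
#' @param coherences Calibrated coherence set (4 ascending values). Use the
#'   set derived from `spec$sigma` (e.g. via [coherence_for_target()] or the
#'   final fit of [calibrate_coherences()]): the partners' accuracy targets
#'   are the model-implied accuracies at `spec$sigma`, and the rejection
#'   sampler can only hit them within 1% when they sit on the grid of
#'   realisable per-coherence accuracies, as in the calibrated task.
#' @param partners Named list of four `partner_profile`s.
#' @param phases Behavioural phases to generate (subset of
#'   `"phase2"`, `"phase3"`, `"phase4"`).
#' @param n_scan_runs Number of scan runs (0 to skip the scan session).
#' @param seed Seed; every session uses a decorrelated child seed.
#' @return Tibble of trial records over all sessions, with columns
#'   `session` (`"phase2"`, `"phase3"`, `"phase4"`, `"scan"`), `run`,
#'   `trial`, design columns, subject columns (`x`, `z`, `choice`,
#'   `correct`, `rt`, `base_report`, `report`, `marker_start`) and social
#'   columns (`partner_choice`, `partner_report`, `group_choice`,
#'   `group_correct`, `selected`, `selection_prob` where defined).
#' @export
generate_subject_sessions <- function(spec, coherences,
                                      partners = default_partner_profiles(),
                                      phases = c("phase2", "phase3", "phase4"),
                                      n_scan_runs = 4, seed = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  phases <- match.arg(phases, c("phase2", "phase3", "phase4"),
                      several.ok = TRUE)
  if (!all(PARTNER_LEVELS %in% names(partners))) {
    abort("`partners` must be a named list covering all four contexts.")
  }

  social_played <- function(trials, sseed) {
    # simulate each partner on its own trials under the accuracy constraint
    trials$partner_choice <- NA_integer_
    trials$partner_report <- NA_integer_
    for (p in PARTNER_LEVELS) {
      rows <- which(trials$context == p)
      ses <- simulate_partner_session(
        trials[rows, c("coherence", "direction")], spec$sigma, partners[[p]],
        seed = child_seed(sseed, match(p, PARTNER_LEVELS)))
      trials$partner_choice[rows] <- ses$trials$choice
      trials$partner_report[rows] <- ses$trials$report
    }
    gd <- group_decision(trials$choice, trials$report,
                         trials$partner_choice, trials$partner_report,
                         seed = child_seed(sseed, 9L))
    trials$group_choice <- gd$group_choice
    trials$group_correct <- gd$group_choice == trials$direction
    trials$selected <- gd$selected == "subject"
    trials$selection_prob <- NA_real_
    trials
  }

  social_background <- function(trials) {
    trials$partner_choice <- NA_integer_
    trials$partner_report <- NA_integer_
    trials$group_choice <- NA_integer_
    trials$group_correct <- NA
    trials$selected <- NA
    ctx <- as.character(trials$context)
    trials$selection_prob <- NA_real_
    for (p in PARTNER_LEVELS) {
      rows <- which(ctx == p)
      if (length(rows)) {
        trials$selection_prob[rows] <- selection_probability(
          trials$report[rows], partners[[p]]$report_probs)
      }
    }
    trials
  }

  sessions <- list()
  for (ph in phases) {
    s <- child_seed(seed, match(ph, c("phase2", "phase3", "phase4")))
    des <- build_design(ph, coherences, seed = child_seed(s, 1L))
    tr <- with_rng(child_seed(s, 2L), subject_pass(des, spec))
    tr <- if (ph == "phase4") social_background(tr)
          else with_rng(child_seed(s, 3L), social_played(tr, child_seed(s, 4L)))
    tr$session <- ph
    tr$run <- 1L
    sessions[[ph]] <- tr
  }
  for (r in seq_len(n_scan_runs)) {
    s <- child_seed(seed, 10L + r)
    des <- build_design("scan_run", coherences, seed = child_seed(s, 1L))
    tr <- with_rng(child_seed(s, 2L), subject_pass(des, spec))
    tr <- social_background(tr)
    tr$session <- "scan"
    tr$run <- r
    sessions[[paste0("scan", r)]] <- tr
  }
  out <- dplyr::bind_rows(sessions)
  dplyr::relocate(out, "session", "run", "trial")
}

#' Specify a synthetic multivoxel-pattern generator
#'
#' Condition means live in voxel space as a sum of a coherence effect, a
#' context effect and their interaction (each a random voxel map per factor
#' level scaled by its effect size); run-specific patterns add Gaussian
#' noise with a configurable voxel covariance.
#'
#' @param n_runs,n_voxels Array dimensions (`>= 2` each).
#' @param es_coherence,es_context,es_interaction Effect sizes (`>= 0`) of
#'   the three mean components, in units of the noise SD.
#' @param noise_sd Within-condition run-to-run noise SD (`> 0`).
#' @param noise_cov `"identity"`, or a voxel covariance matrix for
#'   correlated noise.
#' @return A list of class `pattern_spec`.
#' @export
pattern_spec <- function(n_runs = 4, n_voxels = 40,
                         es_coherence = 0, es_context = 0,
                         es_interaction = 0, noise_sd = 1,
                         noise_cov = "identity") {
  stopifnot(n_runs >= 2, n_voxels >= 2)
  if (es_coherence < 0 || es_context < 0 || es_interaction < 0) {
    abort("effect sizes must be >= 0.")
  }
  assert_positive(noise_sd, "noise_sd")
  if (!identical(noise_cov, "identity")) {
    noise_cov <- as.matrix(noise_cov)
    stopifnot(nrow(noise_cov) == n_voxels, ncol(noise_cov) == n_voxels)
  }
  structure(list(n_runs = n_runs, n_voxels = n_voxels,
                 es_coherence = es_coherence, es_context = es_context,
                 es_interaction = es_interaction, noise_sd = noise_sd,
                 noise_cov = noise_cov),
            class = "pattern_spec")
}

#' Generate a synthetic 4 x 4 condition pattern array
#'
#' @param spec A `pattern_spec`.
#' @param seed Optional seed.
#' @return A `pattern_array` with 16 conditions labelled by
#'   `coherence_level` (1..4) and `context` (the four partners).
#' @export
generate_patterns <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  conds <- tidyr::expand_grid(coherence_level = 1:4,
                              context = PARTNER_LEVELS)
  nc <- nrow(conds)
  nv <- spec$n_voxels
  with_rng(seed, {
    map_k <- matrix(rnorm(4 * nv), 4)
    map_c <- matrix(rnorm(4 * nv), 4)
    map_i <- matrix(rnorm(nc * nv), nc)
    mu <- spec$es_coherence * map_k[conds$coherence_level, ] +
      spec$es_context * map_c[match(conds$context, PARTNER_LEVELS), ] +
      spec$es_interaction * map_i
    arr <- array(NA_real_, c(spec$n_runs, nc, nv))
    L <- if (identical(spec$noise_cov, "identity")) NULL
         else t(chol(spec$noise_cov))
    for (r in seq_len(spec$n_runs)) {
      E <- matrix(rnorm(nc * nv), nc)
      if (!is.null(L)) E <- E %*% t(L)
      arr[r, , ] <- mu + spec$noise_sd * E
    }
    pattern_array(arr, conds)
  })
}

#' Generate synthetic ROI time courses with known effects
#'
#' Builds BOLD-like seed and target region signals as sums of HRF-convolved
#' trial responses plus Gaussian noise. Private confidence drives a
#' response locked to the motion stimulus (early, from the epoch's
#' perspective), reported confidence drives a response locked to the context
#' screen (late), and the target can additionally be coupled to the seed
#' region's trial-by-trial neural amplitude in interaction with the
#' confidence covariates (the generative analogue of a PPI effect).
#'
#' @param trials Tibble with per-trial covariates `private_confidence` and
#'   `report` (e.g. from [private_confidence()] on generated scan trials).
#' @param early_amplitude Weight of (z-scored) private confidence on the
#'   stimulus-locked response.
#' @param late_amplitude Weight of (z-scored) reported confidence on the
#'   context-locked response.
#' @param coupling Named list of seed-coupling weights applied to the
#'   context-locked target response: `seed_private`, `seed_reported`,
#'   `seed_private_reported`.
#' @param iti Mean inter-trial interval (s; onsets jittered uniformly by
#'   +/- 1 s). Intervals under 2 s trigger an overlapping-trial warning.
#' @param stim_to_context Delay from motion stimulus to context screen (s).
#' @param dt_sample Sampling interval of the generated time courses (s).
#' @param noise_sd SD of the additive measurement noise.
#' @param seed_noise_sd SD of the seed region's trial-amplitude variation.
#' @param hrf HRF function of time in seconds.
#' @param seed Optional seed.
#' @return A list of class `synthetic_timecourses`: `seed_roi` and
#'   `target_roi` (tibbles with `time`, `value`), `events` (tibble with
#'   `trial`, `onset_s` = context-screen onset, `stim_onset_s`, covariates
#'   and the seed trial amplitudes), and the generating parameters.
#' @export
generate_timecourses <- function(trials, early_amplitude = 0,
                                 late_amplitude = 0,
                                 coupling = list(seed_private = 0,
                                                 seed_reported = 0,
                                                 seed_private_reported = 0),
                                 iti = 12, stim_to_context = 2,
                                 dt_sample = 0.5, noise_sd = 0.5,
                                 seed_noise_sd = 1, hrf = hrf_double_gamma,
                                 seed = NULL) {
  trials <- as_tibble(trials)
  need <- c("private_confidence", "report")
  if (!all(need %in% names(trials))) {
    abort("`trials` needs `private_confidence` and `report` columns.")
  }
  n <- nrow(trials)
  if (iti - 1 < 2) warn("inter-trial intervals below 2 s: trial responses overlap heavily.")
  cpl <- utils::modifyList(
    list(seed_private = 0, seed_reported = 0, seed_private_reported = 0),
    coupling)
  with_rng(seed, {
    stim_on <- 10 + cumsum(c(0, runif(n - 1, iti - 1, iti + 1)))
    ctx_on <- stim_on + stim_to_context
    t_end <- max(ctx_on) + 25
    time <- seq(0, t_end, by = dt_sample)
    pz <- zscore_apply(trials$private_confidence,
                       zscore_fit(trials$private_confidence))
    rz <- zscore_apply(trials$report, zscore_fit(trials$report))
    s_amp <- 1 + seed_noise_sd * rnorm(n) # seed trial-by-trial neural amplitude
    sz <- zscore_apply(s_amp, zscore_fit(s_amp))

    convolve_events <- function(onsets, amps) {
      out <- numeric(length(time))
      for (i in seq_along(onsets)) {
        out <- out + amps[i] * hrf(time - onsets[i])
      }
      out
    }
    seed_sig <- convolve_events(ctx_on, s_amp) +
      noise_sd * rnorm(length(time))
    target_amp <- late_amplitude * rz +
      cpl$seed_private * sz * pz +
      cpl$seed_reported * sz * rz +
      cpl$seed_private_reported * sz * pz * rz
    target_sig <- convolve_events(stim_on, early_amplitude * pz) +
      convolve_events(ctx_on, target_amp) +
      noise_sd * rnorm(length(time))
    structure(
      list(
        seed_roi = tibble(time = time, value = seed_sig),
        target_roi = tibble(time = time, value = target_sig),
        events = tibble(trial = seq_len(n), onset_s = ctx_on,
                        stim_onset_s = stim_on,
                        private_confidence = trials$private_confidence,
                        report = trials$report, seed_amplitude = s_amp),
        params = list(early_amplitude = early_amplitude,
                      late_amplitude = late_amplitude, coupling = cpl,
                      dt_sample = dt_sample, noise_sd = noise_sd)
      ),
      class = "synthetic_timecourses"
    )
  })
}

#' Simulate reports directly from a cumulative probit model
#'
#' Draws a synthetic subject from the exact model family fitted by
#' [fit_ordinal_probit()]: trial predictors are generated, the latent
#' confidence is `X beta + N(0, 1)` on the fitted (z-scored) predictor
#' scale, and reports follow from the thresholds. Used for
#' parameter-recovery checks where unbiasedness is expected.
#'
#' @param n Number of trials.
#' @param beta Named true weights on the design columns produced by
#'   [ordinal_design()] (names must match; missing names get weight 0).
#' @param tau Five ascending true thresholds.
#' @param seed Optional seed.
#' @return A trials tibble with a `report` column; the realised design and
#'   truth are stored in attributes `"design"`, `"beta"`, `"tau"`.
#' @export
simulate_ordinal_subject <- function(n, beta, tau, seed = NULL) {
  if (length(tau) != 5L || is.unsorted(tau, strictly = TRUE)) {
    abort("`tau` must be 5 strictly ascending thresholds.")
  }
  with_rng(seed, {
    trials <- tibble(
      coherence_level = sample(1:4, n, replace = TRUE),
      rt = rlnorm(n, meanlog = 0, sdlog = 0.4),
      context = factor(sample(CONTEXT_LEVELS, n, replace = TRUE),
                       levels = CONTEXT_LEVELS),
      choice = sample(c(-1, 1), n, replace = TRUE),
      direction = sample(c(-1, 1), n, replace = TRUE),
      marker_start = sample(1:6, n, replace = TRUE)
    )
    des <- ordinal_design(trials)
    b <- setNames(numeric(ncol(des$X)), colnames(des$X))
    if (!all(names(beta) %in% names(b))) {
      abort("`beta` names must match the design columns.")
    }
    b[names(beta)] <- beta
    u <- drop(des$X %*% b) + rnorm(n)
    trials$report <- 1L + rowSums(outer(u, tau, ">"))
    attr(trials, "design") <- des
    attr(trials, "beta") <- b
    attr(trials, "tau") <- tau
    trials
  })
}
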