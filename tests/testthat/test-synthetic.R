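sig <- 0.25
ks4 <- coherence_for_target(sig, c(.6, .7, .8, .9))

test_that("generated studies are reproducible and feed every downstream module", {
  spec <- subject_spec(sig)
  a <- generate_subject_sessions(spec, ks4, seed = 3)
  b <- generate_subject_sessions(spec, ks4, seed = 3)
  expect_identical(a, b)

  # schema: trial tables round-trip through CSV and feed the model code
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(a, path)
  back <- read_trials(path)
  expect_equal(back$report, a$report)
  expect_equal(levels(back$context), levels(a$context))

  fit <- fit_ordinal_probit(a[a$session == "phase4", ])
  expect_true(fit$converged)
  scan <- private_confidence(fit, a[a$session == "scan", ])
  expect_true(all(scan$private_confidence > 1 & scan$private_confidence < 6))

  stats <- update_statistics(scan, every = 20)
  expect_true(all(stats$selection_rate >= 0 & stats$selection_rate <= 1))
  expect_equal(sort(unique(stats$trial)), c(20, 40, 60, 80))

  # group play-out is internally consistent in the played phases
  p2 <- a[a$session == "phase2", ]
  agree <- p2$report > p2$partner_report
  expect_true(all(p2$group_choice[agree] == p2$choice[agree]))
  expect_true(all(p2$selected[agree]))
})

test_that("context shifts propagate to reports in the generated direction", {
  spec0 <- subject_spec(sig, context_shifts = c("low" = 0, "medium-low" = 0,
                                                "medium-high" = 0, "high" = 0))
  tr0 <- purrr::map_dfr(1:6, function(s) {
    generate_subject_sessions(spec0, ks4, phases = "phase4",
                              n_scan_runs = 1, seed = 500 + s)
  })
  m0 <- tapply(tr0$report, as.character(tr0$context), mean)
  expect_lt(max(m0) - min(m0), 0.3) # null shifts: means equal within noise

  spec1 <- subject_spec(sig)
  tr1 <- purrr::map_dfr(1:6, function(s) {
    generate_subject_sessions(spec1, ks4, phases = "phase4",
                              n_scan_runs = 1, seed = 600 + s)
  })
  m1 <- tapply(tr1$report, as.character(tr1$context), mean)
  expect_true(all(diff(m1[c("low", "medium-low", "hidden",
                            "medium-high", "high")]) > 0))

  # choice accuracy tracks the calibrated targets
  acc <- tapply(tr1$correct, tr1$coherence_level, mean)
  n_per <- table(tr1$coherence_level)
  for (lv in 1:4) {
    p <- c(.6, .7, .8, .9)[lv]
    expect_lt(abs(acc[lv] - p), 3 * sqrt(p * (1 - p) / n_per[lv]))
  }
})

test_that("fitted context weights track the generating shifts across subjects", {
  # the probit latent scale differs between subjects, so recovery "up to
  # scale" is a within-subject rank agreement, averaged over seeds
  shifts <- c("low" = -1, "medium-low" = -0.4, "medium-high" = 0.4,
              "high" = 1)
  rhos <- purrr::map_dbl(1:60, function(s) {
    spec <- subject_spec(sig, context_shifts = shifts)
    tr <- generate_subject_sessions(spec, ks4, phases = "phase4",
                                    n_scan_runs = 0, seed = 800 + s)
    fit <- fit_ordinal_probit(tr)
    cor(shifts, unname(fit$beta[fit$context_cols]), method = "spearman")
  })
  expect_gte(mean(rhos), 0.99)
})

test_that("null and structured pattern generators behave as designed", {
  a <- generate_patterns(pattern_spec(), seed = 4)
  b <- generate_patterns(pattern_spec(), seed = 4)
  expect_identical(a, b)
  expect_equal(dim(a$patterns), c(4, 16, 40))
  expect_setequal(unique(a$conditions$context),
                  c("low", "medium-low", "medium-high", "high"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_patterns(a, path)
  back <- read_patterns(path)
  expect_equal(back$patterns, a$patterns)

  expect_error(pattern_spec(es_coherence = -1), ">= 0")
})

test_that("synthetic time courses carry the injected effects at the right latencies", {
  spec <- subject_spec(sig)
  tr <- generate_subject_sessions(spec, ks4, phases = "phase4",
                                  n_scan_runs = 1, seed = 21)
  fit <- fit_ordinal_probit(tr[tr$session == "phase4", ])
  scan <- private_confidence(fit, tr[tr$session == "scan", ])

  # zero amplitudes: encoding betas stay in the null band
  tc0 <- generate_timecourses(scan, noise_sd = 0.3, seed = 1)
  ep0 <- extract_epochs(tc0$target_roi, tc0$events$onset_s)
  bt0 <- pointwise_glm(ep0, scan[, c("private_confidence", "report")])
  expect_lt(max(abs(bt0$beta)), 0.25)

  # private-only: early private peak, flat report trace
  tcP <- generate_timecourses(scan, early_amplitude = 1.5, noise_sd = 0.3,
                              seed = 2)
  epP <- extract_epochs(tcP$target_roi, tcP$events$onset_s)
  btP <- pointwise_glm(epP, scan[, c("private_confidence", "report")])
  bp <- btP[btP$term == "private_confidence", ]
  br <- btP[btP$term == "report", ]
  expect_gt(max(bp$beta), 0.5)
  expect_lt(bp$time[which.max(bp$beta)], 6) # stimulus-locked, pre-HRF-peak
  expect_lt(max(abs(br$beta)), 0.35)

  # overlap warning for short inter-trial intervals
  expect_warning(generate_timecourses(scan, iti = 2.5, seed = 3), "overlap")
})
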