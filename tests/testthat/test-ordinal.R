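true_beta <- c(coherence = 0.8, log_rt = -0.5,
               context_low = -0.8, `context_medium-low` = -0.3,
               `context_medium-high` = 0.3, context_high = 0.8)
true_tau <- c(-1.5, -0.5, 0.2, 0.9, 1.8)

test_that("the likelihood matches a brute-force per-trial computation", {
  tr <- simulate_ordinal_subject(60, true_beta, true_tau, seed = 1)
  des <- attr(tr, "design")
  fit <- fit_ordinal_probit(tr)
  expect_equal(fit$logLik,
               oracle_probit_loglik(fit$beta, fit$tau, des$X, tr$report),
               tolerance = 1e-10)
  # and at arbitrary (non-optimal) parameters through the internal objective
  for (s in 1:5) {
    b <- withr::with_seed(s, rnorm(ncol(des$X), sd = 0.5))
    tau <- sort(withr::with_seed(s + 50, rnorm(5)))
    theta <- c(b, tau[1], log(diff(tau)))
    expect_equal(-confmap:::probit_nll(theta, des$X, tr$report, ncol(des$X)),
                 oracle_probit_loglik(b, tau, des$X, tr$report),
                 tolerance = 1e-10)
  }
})

test_that("the fit agrees with an established ordinal regression", {
  skip_if_not_installed("MASS")
  tr <- simulate_ordinal_subject(400, true_beta, true_tau, seed = 2)
  fit <- fit_ordinal_probit(tr)
  d <- as.data.frame(attr(tr, "design")$X)
  names(d) <- make.names(names(d))
  d$y <- factor(tr$report, levels = sort(unique(tr$report)))
  ref <- MASS::polr(y ~ ., data = d, method = "probit")
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # hidden-context trials anchor the baseline, so weights are directly
  # comparable (polr's intercept direction is pinned the same way)
  nm <- c("coherence", "log_rt", "context_low", "context_medium.low",
          "context_medium.high", "context_high")
  ours <- fit$beta
  names(ours) <- make.names(names(ours))
  expect_equal(unname(ours[nm]), unname(coef(ref)[nm]), tolerance = 1e-3)
  expect_equal(unname(fit$tau), unname(ref$zeta), tolerance = 1e-3)
})

test_that("the null model reproduces the marginal report CDF in its thresholds", {
  zero_beta <- setNames(rep(0, length(true_beta)), names(true_beta))
  tr <- simulate_ordinal_subject(2000, zero_beta, true_tau, seed = 3)
  fit <- fit_ordinal_probit(tr)
  expect_lt(max(abs(fit$beta)), 0.12)
  emp_cdf <- cumsum(tabulate(tr$report, 6L) / nrow(tr))[1:5]
  expect_equal(fit$tau, qnorm(emp_cdf), tolerance = 0.05)
  expect_true(fit$converged)

  expect_error(
    fit_ordinal_probit(dplyr::mutate(tr, report = 3L)),
    "2 distinct")
})

test_that("predicted report distributions are proper and behave in the limits", {
  tr <- simulate_ordinal_subject(150, true_beta, true_tau, seed = 4)
  fit <- fit_ordinal_probit(tr)
  probs <- predict_report_distribution(fit, tr)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-12)

  # hand-built model: eta = 0 with symmetric thresholds -> symmetric pmf
  sym <- fit
  sym$beta[] <- 0
  sym$tau <- c(-2, -1, 0, 1, 2)
  p <- predict_report_distribution(sym, tr[1, ])
  expect_equal(p[1, 1:3], rev(p[1, 4:6]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # extreme eta concentrates on report 6
  hi <- fit
  hi$beta["coherence"] <- 50
  p6 <- predict_report_distribution(hi, tr[which.max(tr$coherence_level)[1], ])
  expect_gt(p6[1, 6], 0.999)
})

test_that("private confidence is exactly invariant to context labels", {
  spec <- subject_spec(0.25)
  ksc <- coherence_for_target(0.25, c(.6, .7, .8, .9))
  tr <- generate_subject_sessions(spec, ksc, seed = 9)
  fit <- fit_ordinal_probit(tr[tr$session == "phase4", ])
  scan <- tr[tr$session == "scan", ]
  pc <- private_confidence(fit, scan)
  expect_true(all(pc$private_confidence >= 1 & pc$private_confidence <= 6))

  shuffled <- scan
  shuffled$context <- withr::with_seed(1, sample(shuffled$context))
  pc2 <- private_confidence(fit, shuffled)
  expect_identical(pc$private_confidence, pc2$private_confidence)

  # reported confidence shows the injected context shifts, private does not
  sig_ctx <- !is.na(scan$context) & scan$context != "hidden"
  rep_fit <- lm(scan$report[sig_ctx] ~ as.character(scan$context[sig_ctx]))
  priv_fit <- lm(pc$private_confidence[sig_ctx] ~
                   as.character(scan$context[sig_ctx]))
  # context explains reports but only residual sampling imbalance in the
  # context-free private estimate
  expect_gt(max(abs(coef(rep_fit)[-1])), 0.5)
  expect_lt(max(abs(coef(priv_fit)[-1])),
            max(abs(coef(rep_fit)[-1])) / 2)
  expect_lt(max(abs(coef(priv_fit)[-1])), 0.4)

  # zeroing context weights that are already zero changes nothing
  zero_beta <- setNames(rep(0, length(true_beta)), names(true_beta))
  tr0 <- simulate_ordinal_subject(300, zero_beta[1:2], true_tau, seed = 5)
  f0 <- fit_ordinal_probit(tr0)
  f0z <- f0
  f0z$beta[f0z$context_cols] <- 0
  full <- predict_report_distribution(f0z, tr0) %*% (1:6)
  cf <- private_confidence(f0, tr0)$private_confidence
  expect_equal(drop(full), cf, tolerance = 1e-10)
})

test_that("uniform predicted distributions give expectation 3.5", {
  tr <- simulate_ordinal_subject(10, true_beta, true_tau, seed = 6)
  # only the model skeleton matters here; 10 trials may trigger separation
  fit <- suppressWarnings(fit_ordinal_probit(tr))
  uni <- fit
  uni$beta[] <- 0
  uni$tau <- qnorm(seq(1 / 6, 5 / 6, by = 1 / 6))
  pc <- private_confidence(uni, tr)
  expect_equal(pc$private_confidence, rep(3.5, nrow(tr)), tolerance = 1e-10)
})

test_that("group-level t-test behaves under null, sign flip and degeneracy", {
  x <- withr::with_seed(7, rnorm(28, mean = 0.3))
  res <- group_level_test(x)
  expect_equal(res$df, 27)
  flipped <- group_level_test(-x)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p_value, res$p_value)

  expect_warning(deg <- group_level_test(rep(2, 10)), "variance")
  expect_true(deg$degenerate)
  expect_equal(deg$t, Inf)
  expect_error(group_level_test(1.2), "2 subjects")

  # type-I error calibration at alpha = .05
  rej <- withr::with_seed(8, {
    mean(vapply(1:10000, function(i) {
      group_level_test(rnorm(28))$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rej - 0.05), 0.006)
})

test_that("fitted models round-trip through JSON", {
  tr <- simulate_ordinal_subject(150, true_beta, true_tau, seed = 10)
  fit <- fit_ordinal_probit(tr)
  path <- withr::local_tempfile(fileext = ".json")
  write_ordinal_model(fit, path)
  back <- read_ordinal_model(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$tau, fit$tau)
  expect_equal(predict_report_distribution(back, tr),
               predict_report_distribution(fit, tr))
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$beta) + 5)
  expect_true(glance(fit)$converged)
})
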