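# confmap

Tools for studying how *private* decision confidence is mapped onto
*public* confidence reports in social perceptual decision making — and for
validating, end to end on synthetic data, the behavioural and neuroimaging
analyses that such studies rely on.

## The problem

In a social perceptual task, two players each judge the direction of a
random-dot-motion stimulus and report confidence on a 1–6 scale; the
decision made with higher reported confidence becomes the group decision.
Because different partners report confidence differently, the
reward-maximising strategy is to *match the partner's mean confidence* —
so the very same internal sense of confidence should be reported
differently depending on who the partner is. Separating the
context-invariant ("private") component of confidence from the
context-dependent ("public") report is the core statistical problem this
package addresses, for researchers in computational cognitive neuroscience
who want to simulate such designs or analyse data from them.

## What is inside

- **SDT simulator and calibration** (`simulate_evidence()`, `decide()`,
  `internal_confidence()`, `fit_sigma()`, `coherence_for_target()`,
  `calibrate_coherences()`). Evidence on each trial is
  *x* ~ N(*dk*, σ) with direction *d* ∈ {−1, +1} and coherence *k*; choice
  is sign(*x*), internal confidence is *z* = |*x*|, and accuracy is
  Φ(*k*/σ). A two-block procedure fits σ by least squares and selects
  coherences hitting 60/70/80/90% accuracy.
- **Partner agents** (`partner_profile()`, `simulate_partner_session()`,
  `thresholds_from_distribution()`). Partners share the subject's choice
  accuracy (rejection sampling keeps each session within 1% of target at
  every coherence) but differ in mean confidence; report thresholds are
  placed in *z*-space by rank so the report histogram matches its target
  exactly.
- **Task engine** (`build_design()`, `group_decision()`,
  `selection_probability()`, `sweep_group_accuracy()`,
  `update_statistics()`). Factorial designs for every task phase
  (including 80-trial scan runs: 4 coherences × 5 contexts × 4
  repetitions), the higher-confidence group rule, and the strategy
  experiment showing group accuracy peaks where the subject matches the
  partner's mean confidence.
- **Confidence model** (`fit_ordinal_probit()`, `private_confidence()`).
  Cumulative probit regression of reports, P(r ≤ j) = Φ(τ_j − **x**'β),
  with coherence, log RT and context-dummy predictors; private confidence
  is the expected report after setting the fitted context weights to zero
  — an out-of-sample counterfactual that is exactly invariant to context
  labels.
- **Multivariate pattern analysis** (`sdrdm()`, `edi()`,
  `noise_covariance()`, `signrank_group_test()`). Split-data RDMs of
  cross-validated Mahalanobis distances; the exemplar discriminability
  index EDI = mean(off-diagonal) − mean(diagonal), positive when patterns
  are more stable within than between conditions, tested one-tailed across
  subjects.
- **Time-course and PPI regressions** (`extract_epochs()`,
  `pointwise_glm()`, `ppi_glm()`, `group_timepoint_test()`). Trial-locked
  12 s epochs at 0.144 s resolution, per-timepoint encoding betas, and
  psychophysiological interactions between a seed region and confidence
  covariates.
- **Synthetic-data generators** (`generate_subject_sessions()`,
  `generate_patterns()`, `generate_timecourses()`) with known ground truth
  for every stage.

See `vignettes/confidence-mapping.Rmd` for the full methods account.

## Worked example

```r
library(confmap)

# calibrate stimulus coherences for a simulated observer with sigma = 0.25
cal <- calibrate_coherences(sigma_true = 0.25, seed = 11)
cal
#> Two-block stimulus calibration
#>   sigma (block 1): 0.2205
#>   sigma (block 2): 0.3321
#>   final coherences: 0.084, 0.174, 0.279, 0.426
#>   target accuracies: 60%, 70%, 80%, 90%

# a low-confidence partner with the same choice accuracy
sigma_hat <- cal$sigma_block2
ses <- simulate_partner_session(
  stimuli = data.frame(coherence = rep(cal$coherences, each = 40),
                       direction = rep(c(-1, 1), 80)),
  sigma = sigma_hat, profile = default_partner_profiles()$low, seed = 12)
ses
#> Partner session (low): 160 trials, 2715 attempt(s)
#>   mean confidence 2.13; max accuracy deviation 0.000

# a full synthetic subject: behaviour phases plus four scan runs
spec   <- subject_spec(sigma = sigma_hat, coherences = cal$coherences)
trials <- generate_subject_sessions(spec, cal$coherences, seed = 13)

# fit the confidence model on the final behavioural phase, then estimate
# private confidence for the scan session
fit  <- fit_ordinal_probit(trials[trials$session == "phase4", ])
scan <- private_confidence(fit, trials[trials$session == "scan", ])

round(tapply(scan$report, as.character(scan$context), mean), 2)
#>   low  medium-low  hidden  medium-high  high
#>  2.28        3.08    3.62         3.69  4.52
round(tapply(scan$private_confidence, as.character(scan$context), mean), 2)
#>   low  medium-low  hidden  medium-high  high
#>  3.14        3.41    3.57         3.32  3.50
```

The calibration print shows the fitted noise level and the coherences that
hit the four target accuracies; the partner session reproduces its target
report histogram exactly (mean report 2.13 for the "low" partner) while
deviating 0.000 from the target accuracy at every coherence. In the scan
session the *reported* confidence is strongly ordered by partner
(2.28 → 4.52), while the model-based *private* confidence is flat across
partners (3.1–3.6): the counterfactual removes exactly the contextual
component of the report.

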