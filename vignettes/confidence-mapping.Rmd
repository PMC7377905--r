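---
title: "From private confidence to public reports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From private confidence to public reports: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confmap)
```

confmap simulates and analyses a social perceptual decision task in which
the mapping from an internal sense of confidence to an overt confidence
report depends on the social context. This vignette is the package's
methods account: the generative models, the estimators, the tunable
parameters and why their defaults are what they are, the numerical
choices, and what the synthetic-data tests do and do not establish.

## 1. The perceptual model and stimulus calibration

Each trial presents a random-dot-motion stimulus with coherence $k$ (the
fraction of coherently moving dots, in $[0,1]$) and true direction
$d \in \{-1, +1\}$ (left/right). The observer receives a single noisy
evidence sample

$$x \sim \mathcal{N}(dk, \sigma),$$

chooses left if $x < 0$ and right if $x > 0$, and derives internal
confidence $z = |x|$, which is monotonically related to the probability
that the choice is correct given the evidence. The implied psychometric
function is $P(\text{correct}) = \Phi(k/\sigma)$.

Two numerical conventions are worth stating. The measure-zero tie $x = 0$
is resolved by a fair coin under the supplied seed. And all randomness in
the package flows through explicit `seed` arguments evaluated in a local
RNG scope (`withr::with_seed`), so every stochastic operation is
bit-reproducible and never perturbs the caller's RNG stream.

Calibration proceeds in two blocks, as in the task it models: block 1
presents the prespecified set $K = \{.03,.06,.12,.24,.48\}$, 20 trials per
direction per level; $\sigma$ is then fitted by minimising the sum of
squared errors between $\Phi(k/\sigma)$ and observed accuracy. Because the
objective is one-dimensional and cheap, `fit_sigma()` uses a dense
log-spaced grid (2000 points over $[10^{-3}, 10]$) with golden-section
refinement around the grid minimum rather than a general-purpose
optimiser; this removes any dependence on optimiser tolerances and makes
the estimate deterministic given the data. Degenerate inputs (all
accuracies at or below chance) and boundary solutions are flagged with a
warning rather than returned silently. Block 2 presents the coherences
$k_p = \sigma \Phi^{-1}(p)$ for the targets $p = .6,.7,.8,.9$ (25 trials
per direction per level) and is refitted *on its own data alone* — the
procedure's description leaves pooling open, and refitting on block 2
keeps the final estimate closest to the stimulus range actually used in
the task. The final coherence set and fitted $\sigma$ are carried forward
together; downstream, accuracy targets are always the model-implied
accuracies at that same $\sigma$, which is what makes them exactly
attainable in finite sessions.

With 200 trials per block, $\sigma$ is identified to roughly $\pm 10\%$;
consequently the *realised* accuracies under the generating noise level
can deviate from the nominal targets by several percentage points. All
self-consistency guarantees in the package (and its tests) are therefore
stated under the fitted noise parameter, mirroring how the task itself
uses the estimate.

## 2. Partner agents

Partners are SDT agents with the subject's (fitted) $\sigma$ whose
confidence-report distributions are imposed exactly. Two mechanisms
interact:

* **Accuracy constraint.** A whole session's evidence vector is redrawn
  until the realised accuracy is within `tolerance` (default 1%) of the
  target at *every* coherence level — whole-session rejection rather than
  per-trial editing, so the accepted evidence still follows the SDT
  generative law conditional on acceptance. The constraint is applied per
  coherence level, pooled over directions. With 40 trials per level the
  realisable accuracies form a 2.5-point grid, so a 1% tolerance forces
  exact target counts; acceptance probabilities are a few in $10^4$ and
  the default budget of 10,000 attempts fails only rarely (the error
  names the coherence level that most often violated the constraint).
* **Exact report histograms.** Given the accepted internal-confidence
  values $z$ and target counts over reports 1..6,
  `thresholds_from_distribution()` assigns reports by rank of $z$ (ties
  broken by trial index) and returns the five implied thresholds. Rank
  assignment guarantees the histogram exactly even with tied $z$, where
  interval thresholds alone could not.

The published partner distributions are not tabulated anywhere we can
read them from, so the defaults are *surrogate values*: discretised
Gaussians on the 1..6 scale with matched spread and means near 2, 3, 4
and 5 for the low / medium-low / medium-high / high partner. Their means
are strictly ordered while their target accuracy is identical — the
defining property of the partner set.

## 3. Task designs and the group rule

`build_design()` reproduces each phase's factorial arithmetic exactly:
calibration blocks (200 trials each), the block-wise partner phase (4
cycles of A-B-C-D blocks of 10; 160 trials), the interleaved phase (4 ×
40), the hidden-context phase (5 × 40 = 200) and scan runs (4 coherences
× 5 contexts × 4 repetitions = 80). Coherence is counterbalanced within
context; directions split 50/50 within every condition cell (randomised
only when a cell is odd-sized); order is randomised under the seed with
the block structure preserved where it exists.

The group rule selects the decision reported with higher confidence; ties
are broken by a fair coin, since the task description never specifies a
tie rule. Consistently, the analytic probability that the subject's
decision is selected given report $r$ and the partner's report
distribution is $P(r_p < r) + \tfrac{1}{2} P(r_p = r)$. The running
selection statistics shown to subjects (`update_statistics()`) average
those per-trial probabilities per partner at a configurable cadence —
every 40 trials in the prescan session, every 20 in the scan session, the
two cadences the task reports — resetting at run boundaries.

`sweep_group_accuracy()` runs the strategy experiment: a subject policy
(a discretised-Gaussian report distribution with target mean $m$, imposed
by the same rank-thresholding machinery as the partners) plays against a
partner over a grid of $m$. Group accuracy peaks where the subject
matches the partner's mean confidence: reporting above the partner makes
the group follow the subject even when the partner's evidence was
stronger, and symmetrically below. Numerically the maximum is shallow —
within a grid step of the peak the curve moves by less than 0.1
percentage point for the extreme partners — so the sweep shares one set
of evidence draws across all grid points (common random numbers). With
independent draws per point the argmax location would be dominated by
Monte-Carlo noise at any affordable simulation count.

## 4. The confidence model and counterfactual private confidence

Reports are modelled by cumulative ("ordered") probit regression,

$$P(r \le j \mid \mathbf{x}) = \Phi(\tau_j - \mathbf{x}'\beta), \qquad
  \tau_1 < \dots < \tau_5,$$

with predictors: contrast-coded coherence ($\{-1.5,-0.5,.5,1.5\}$,
z-scored), log reaction time (z-scored), one dummy per signalled context,
and optional z-scored nuisance terms (choice, motion direction, marker
start position). z-scoring parameters are always computed on the fitting
set and *re-applied unchanged* to held-out scan data; the alternative
(re-scaling on the scan set) would let the scan session's covariate
distribution leak into the counterfactual.

**Identification.** With every fitted trial carrying one of the four
context dummies, the dummies sum to one on each row and are collinear
with the thresholds: $\beta_{\text{context}} + c$, $\tau + c$ is the same
model for any $c$, so "set the context weights to zero" would be
ill-defined. The final behavioural phase contains hidden-context trials;
keeping them in the fitting set as all-zero-dummy rows anchors the
baseline and makes the context weights (and hence the counterfactual)
identified. `ordinal_design()` therefore keeps hidden trials by default
and `fit_ordinal_probit()` warns when no baseline rows are present.

**Fitting.** The negative log-likelihood is minimised by BFGS with
analytic gradients. Threshold ordering is enforced by reparameterising
the gaps $\tau_{j+1} - \tau_j$ as exponentials, giving an unconstrained
smooth problem; the first start sets $\beta = 0$ with thresholds at the
probit-transformed marginal report CDF (the closed-form null-model
solution), and two jittered restarts guard against local minima.
Non-convergence and apparent separation (a diverging weight) raise
warnings and set flags. On identified designs the fit matches
`MASS::polr(method = "probit")` to within optimiser tolerance — polr
serves as an independent cross-check in the test suite, never as the
implementation.

**Private confidence.** The model fitted on the final behavioural phase
is applied to scan trials with the context weights forced to zero; the
expectation $\sum_j j \, P(r = j)$ of the resulting report distribution
is the per-trial private-confidence estimate. It is invariant to the
trials' context labels *by construction* (the dummies are multiplied by
zeroed weights), a property the tests assert exactly, and hidden-context
scan trials are handled identically since their dummies are already zero.
At 200 fitting trials the estimate tracks the generative context-free
expectation with rank correlations around 0.97; the residual gap is
estimation noise in $\hat\beta, \hat\tau$ (of order $\sqrt{p/n}$ in the
latent metric), not a property of the counterfactual itself, which is
exact when evaluated at the true parameters.

## 5. Pattern dissimilarity and the exemplar discriminability index

Condition-by-run voxel patterns (estimates per scan run for the 16
coherence × context conditions) are compared across runs: for run $i$,
entry $(p, q)$ of the split-data RDM is the Mahalanobis distance between
condition $p$'s pattern in run $i$ and condition $q$'s pattern averaged
over the other runs; run-specific matrices are averaged. Diagonal entries
are cross-run *within*-condition distances and are not zero. The exemplar
discriminability index,

$$\mathrm{EDI} = \overline{d}_{\text{off-diagonal}} -
  \overline{d}_{\text{diagonal}},$$

is positive when patterns are more stable within than between conditions,
i.e. when the region carries condition information; under exchangeable
condition labels its expectation is zero, which the null simulations
confirm.

Numerical choices: the voxel noise covariance is estimated with shrinkage
toward the diagonal of the sample covariance, with an analytic
(Ledoit–Wolf/Schäfer–Strimmer-style) weight, so the matrix is invertible
even with fewer residual observations than voxels; an identity covariance
is available for oracle testing (where the distances reduce to plain
cross-validated Euclidean distances and are checked against a brute-force
double loop). Distances are unsquared by default with a `squared` option
— the sign properties of the EDI hold either way, and which convention
the reference analyses used is not stated. Sub-space analyses (coherence
only, context only) average condition patterns over the other factor
within each run; for a linear pattern model on these balanced designs
this is equivalent to re-estimating patterns from the pooled trials, and
it is the cheaper and more transparent of the two routes. Group
inference is a one-tailed Wilcoxon signed-rank test against zero (the
EDI should not be negative in expectation): zeros dropped, ties
mid-ranked, exact null for $n \le 25$ after zero-dropping and the
continuity-corrected normal approximation above — the standard
conventions, wrapped around `stats::wilcox.test`.

## 6. ROI time courses and PPI

Trial-locked analysis extracts a 12 s window (2 s before to 10 s after
the event onset) from each ROI's time course at 0.144 s resolution by
linear interpolation, after removing slow drifts with a discrete-cosine
basis (128 s cutoff) — the conventional fMRI high-pass. Trials whose RT
is more than 2.5 SD from the grand mean are excluded first (with the
convention that a zero-SD session excludes nothing). A linear regression
at each timepoint, with per-subject z-scored covariates, yields one beta
time course per predictor; the PPI model predicts the target region from
seed activity, private confidence, reported confidence and all their
products, controlling every main effect, and reads out the three
seed-interaction traces. Group-level inference is a one-sample t-test per
timepoint at $\alpha = .05$ *uncorrected across timepoints* — stated
prominently because it mirrors the reference convention, not because it
is conservative; window averages (e.g. 6–8 s post-onset) are provided for
summary tests.

## 7. Synthetic data: what it emulates and what it does not

`generate_subject_sessions()` plays a specified subject through all
phases: SDT choices and internal confidence; a fixed five-threshold
report policy (thresholds placed deterministically at quantiles of the
model-implied $|x|$ distribution so the baseline report distribution is
bell-shaped and centred mid-scale); additive context shifts per partner
(defaults $-1, -0.4, +0.4, +1$ report units, hidden $= 0$), applied with
stochastic rounding so fractional shifts move the mean report by exactly
the nominal amount, then clipped to 1..6; and reaction times
$\mathrm{RT} = b + s/(|x| + \varepsilon)\cdot e^{\eta}$,
$\eta \sim \mathcal{N}(0, \text{sdlog})$, so that log RT carries
confidence information beyond coherence — the premise that makes RT a
useful predictor in the confidence model. Partner play-out uses the full
constraint machinery in the partner-identified phases and the analytic
selection probabilities in the hidden phase and scan runs, as in the
task.

`generate_patterns()` builds 16-condition pattern arrays as
$\mu_{kc} = e_K a_k + e_C b_c + e_{KC} g_{kc}$ in voxel space (random
maps per factor level scaled by effect sizes) plus run noise with a
configurable covariance. `generate_timecourses()` sums HRF-convolved
trial responses — the canonical double-gamma (response shape 6,
undershoot 16, ratio 1/6, mode near 5 s) — with private confidence
driving the stimulus-locked response, reported confidence the
context-screen-locked response (2 s later), and optional seed-coupling
terms that are the generative analogue of a PPI effect; it warns when
inter-trial intervals fall below 2 s. The generator samples at 0.5 s by
default: fine enough that epoch interpolation resolves the ~2 s latency
difference the recovery tests check, while keeping simulated cohorts
cheap.

A simulated cohort of 28 subjects mirrors common group sizes in this
literature and is the default for group-level calibration checks.

What the generators deliberately do **not** emulate: learning dynamics
(partners are static and subjects' context shifts are fixed parameters,
not acquired — how real subjects acquire them is outside the model);
head-motion or physiological noise in the time courses; spatial structure
of real BOLD noise beyond a voxel covariance; and any attempt to match
empirically reported effect sizes. Passing tests therefore establish that
the estimators are correct and calibrated *under the assumed generative
family* — unbiased weight recovery, exact counterfactual invariance, null
EDI calibration at the nominal 5% level, correct sign/latency recovery —
not that real data satisfy those assumptions.

## 8. Problem sizes and runtime conventions

The simulation scales used by the shipped tests are part of the package's
design: 100 replicate subjects at 200 trials for parameter recovery (the
length of the final behavioural phase), 2000 replicate cohorts of 28 for
null-EDI calibration, $10^5$ Monte-Carlo trials for psychometric checks,
and $10^5$ simulations per grid point (with common random numbers) for
the strategy sweep. They were chosen so each check has the statistical
resolution its tolerance needs while the whole suite runs in a few
minutes on a single core.

## 9. Known limitations

* The ordinal model is fitted per subject; no hierarchical pooling across
  subjects is provided (matching the reference analyses).
* Private confidence inherits the estimation noise of a 200-trial fit
  (§4); applications with shorter fitting sessions should expect
  proportionally noisier counterfactuals.
* The EDI machinery assumes the same condition set in every run and does
  not implement searchlight mapping or first-level GLM estimation from
  raw BOLD; inputs are condition-by-run pattern estimates.
* Pattern arrays serialise to long-format CSV (readable anywhere) rather
  than a binary container.
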