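---
title: "Methods: motor growth charts and developmental age prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motor growth charts and developmental age prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `motorchart`, the
choices that were genuinely open when the package was designed, and what
its synthetic validation does and does not demonstrate.

## The measurement model

The raw input is a frame-level label stream: a wearable classifier
assigns each 2.3-second frame (50% overlap, so a 1.15 s hop; one hour is
3130 frames) one of six postures and one of seven movement types, plus
binary carried and signal-quality flags. The package deliberately starts
*after* classification — classifier training, raw inertial data and
acquisition are out of scope — so any system emitting the same schema
(`frame_index`, `posture`, `movement`, `carried_flag`, `quality_flag`)
can be analysed.

Frames enter the analysis only if they pass three masks: usable signal
quality, not caregiver-carried, and free play ("playtime"). Playtime is
detected by a binary classifier on 10-minute (520-frame, 50% overlap)
super-segment windows, each summarized by its posture and movement
category distributions. We use ridge-penalized logistic regression as
the regularized linear classifier; window decisions are mapped back to
frames by majority vote over the covering windows with ties counted
positive (the window decision rule is not otherwise determined, and a
tie means at least one covering window saw play). Low-quality frames are
removed *before* windowing, since quality-based discarding happens
upstream of every other classification. Recordings retaining under
20 minutes of playtime are excluded from feature computation — a
configurable floor below which distribution estimates are too noisy —
while the variability analysis applies its own, stricter, strictly-
greater-than-2-hour rule.

A recording's feature vector concatenates the posture occupancy
distribution (6 values summing to 1) with the posture-conditioned
movement distribution (6 × 7, each observed row summing to 1), flattened
in a fixed row-major order: 48 dimensions. Postures never observed in a
recording get all-zero conditional rows rather than `NA` or row
deletion, keeping the feature space fixed-dimensional across recordings;
the alternative (dropping absent rows) would make the regression input
dimension data-dependent and was rejected.

## Developmental age prediction

DAP asks: *what age most plausibly produced this motor (or physical)
measurement?* We implement it as the posterior mean of a forward
Gaussian-process regression of chronological age on the feature vector —
the standard GPR reading — with an isotropic radial-basis-function
kernel plus a white-noise term:

$$k(x, x') = \sigma_f^2 \exp\!\left(-\tfrac{\lVert x-x'\rVert^2}{2\ell^2}\right) + \sigma_n^2\,\mathbf{1}[x = x'].$$

An inverse-model reading (a likelihood over age given features) is also
admissible; the forward reading was chosen because it directly yields
the predictive mean and SD in months and needs no age prior. Features
and the age target are standardized internally (constant feature cells —
e.g. movement types that never occur in a posture — are centred but not
scaled, and contribute nothing to kernel distances); predictions are
re-expressed in months. Hyperparameters maximize the log marginal
likelihood via L-BFGS-B on log-parameters with analytic gradients and
five seeded restarts by default (the first start is data-driven: signal
variance from the target variance, squared length-scale from the median
pairwise squared distance, noise at 10% of target variance; the rest are
unit-SD log-space jitters). The same seed reproduces the fit exactly.
The predictive SD includes the noise term, i.e. it describes a new
*measurement*, not the latent mean.

Evaluation is always subject-grouped: leave-one-subject-out by default,
or `k` subject-grouped folds for large cohorts (used for the physical
cohorts, where one fold per subject would cost thousands of refits and
change nothing statistically). Every fold asserts that no subject
appears on both sides. Physical DAP applies the identical machinery to
1-D (length, weight, or head circumference) or 3-D (combined) feature
vectors.

## Growth charts

A chart is a 4PL sigmoid fit of DAP versus age,
$f(x) = L + (U-L)/(1+e^{-k(x-x_0)})$, by least squares
(Levenberg–Marquardt) with data-driven multi-start: $L=\min$, $U=\max$,
$x_0=$ median age, $k \in \{0.2, 0.5, 1\}$ (mirrored when the response
decreases); the lowest-SSE start wins and a coarse brute-force lattice
is used in the tests as an independent check that the optimizer is not
trapped. Any 4PL reparameterization produces the same fitted curve, so
the goodness-of-fit metrics do not depend on this choice. A
(near-)constant response returns a flat degenerate fit with `R² = 0` by
convention instead of erroring. The sigmoid form reflects the motor
scale's saturation once fluent walking is achieved; it accommodates the
nearly-linear physical DAP trajectories as a special case (midpoint
outside the range).

Goodness-of-fit is reported at three levels, with σ defined as the RMS
residual in months (not an n−1 SD) so the ±1σ chart band and the metric
coincide:

* **raw** — every measurement against the curve;
* **monthly means** — bin-mean DAP against the curve at the bin-mean
  age, bins `[m, m+1)` months (for exact data a small Jensen gap
  remains, since the mean of the curve is not the curve at the mean);
* **ID-controlled** — after removing per-subject random intercepts,
  fitted by REML on the residuals (`lme4`), a two-stage correction that
  matches treating the mixed model as a *serial-measurement correction*
  of an already-fitted mean curve rather than a joint nonlinear mixed
  fit. σ here is the REML within-subject residual SD: the RMS of the
  empirical corrected residuals systematically underestimates the
  within-subject noise because the fitted intercept absorbs each
  subject's mean residual (by a factor √(1−1/m) for m visits), and the
  model-based estimate is free of that bias. With no repeated subjects
  the correction degrades to raw residuals with a warning.

Confidence intervals are percentile bootstrap (default N = 10,000 for
standalone use; charts default to 2,000, and the acceptance script uses
1,000 — CI endpoints move by far less than the effects of interest well
before that). Raw/grouped metrics and the four curve parameters resample
recordings; ID-controlled metrics resample whole subjects, because the
random-intercept structure lives at the subject level. Resamples on
which a metric is undefined (e.g. a degenerate refit) are redrawn and
counted.

## Variability and longitudinal tracking

Recordings with strictly more than 2 h of playtime are split into
consecutive non-overlapping 1-h playtime epochs (trailing partial epoch
discarded; the threshold is read on playtime content, not wall-clock
time, since only playtime frames carry information). Each epoch gets its
own features and DAP; all within-recording epoch pairs contribute a
difference, and the per-epoch noise SD is SD(differences)/√2, because a
difference of two independent equal-variance epochs carries twice the
per-epoch variance. The differences are standardized by their sample
moments and tested against a standard normal (one-sample K–S); note
that sample-moment standardization makes this test conservative under
the null (the Lilliefors effect), which the test suite asserts
explicitly. The "noise versus age" correlation uses absolute
differences (a noise *level* against age); a signed variant is
available by flag.

For tracking, every within-subject ordered pair (t₁ > t₀) yields
(Δage, ΔDAP); monthly Δage bins report mean and SD of ΔDAP, bins with
fewer than 3 pairs are flagged and excluded from the monotonicity
summary.

## The synthetic cohort generator

No real cohort of this kind is openly distributable, so validation runs
on synthetic data whose generating model matches what the analyses
assume:

* **Developmental age** for subject *i*, session *r* at age *t* is
  `d = t + δᵢ + ηᵣ`, with `δᵢ ~ N(0, σ_dev²)` and `ηᵣ ~ N(0, σ_sess²)`.
  Defaults σ_dev = 1.0 and σ_sess = 0.85 months are back-calculated so
  the generated motor chart spreads land where home wearable cohorts
  do (raw ≈ 1.4, ID-controlled ≈ 0.97, intra-session ≈ 0.85 months):
  σ_dev ≈ √(1.4² − 0.97²) ≈ 1.0.
* **Postures** are drawn from `softmax(z_p(d))` with logistic-in-age
  logits whose defaults (one documented YAML file,
  `inst/extdata/synth_defaults.yaml`) reproduce the canonical ordering:
  supine declines first, prone next, a transient crawl-posture peak,
  then persistent rises of sitting and finally standing. **Movements**
  within a posture follow a cumulative-logit ordinal model
  (still < proto < elementary < fluent) whose latent maturity increases
  linearly in `d`, so the fluent share is strictly increasing — plus
  small fixed probabilities for pivot/roll/transition where applicable.
* **Session structure**: free-play and other awake periods alternate as
  long blocks (mean 30 min) while carried and low-quality periods are
  short interruptions (mean 5 min); block lengths are geometric and
  type draw probabilities are scaled by inverse mean length so expected
  time shares equal the configured fractions (defaults 0.26 playtime,
  0.10 carried, 0.20 low quality — the hours accounting of a realistic
  home-recording cohort: roughly 80% usable signal and a quarter of the
  day's recording in free play). Non-play and carried periods emit
  still-dominated,
  age-invariant label distributions — that contrast is what makes
  windows discriminable. Consecutive frames repeat with probability
  `p_stay = 0.9` (≈ 11 s mean dwell), emulating the autocorrelation of
  real behaviour and of overlapping frames.
* **Physical growth** uses strictly increasing exponential-approach
  median curves per modality with subject random intercepts and
  measurement error (`m = μ(t) + bᵢ + e`), sampled on a jittered clinic
  visit schedule. Default noise SDs give length the tightest age
  information and weight/head circumference the loosest — the ordering
  familiar from paediatric growth screening, where stunted length is the
  sharpest growth marker.
* Cohort plan defaults: 61 subjects, ages 4–18 months, 1–7 recordings
  each, sessions uniform on 1.4–14.2 h (mean 7.8 h).

What the generator does **not** emulate: real classifier confusion
(labels are drawn from the true state distribution, so epoch-level DAP
noise on synthetic data reflects finite-sample variation only and lands
below the injected between-session situational noise), biomechanics or
kinematic quality,
preterm-corrected age, day-scale test–retest structure, cultural or
environmental covariates, and any correlation between motor and
physical development (they are generated independently). Passing
synthetic tests therefore demonstrates that the *pipeline recovers what
the model injects* — unbiased age mapping, correct variance components,
replicable charts — not that the models are adequate for any particular
real cohort.

## Numerical and scale choices

* Hours↔frames conversions use 3130 frames/hour (floor of 3600/1.15);
  days→months conversions use 30.4375 days/month.
* GP optimization bounds log-parameters within ±6 log-units of the
  data-driven start and floors the noise variance at 10⁻⁶ (plus a 10⁻¹⁰
  jitter on the kernel diagonal) to keep Cholesky factorizations
  well-posed.
* `fitSigmoid` requires ≥ 5 points and non-constant ages; `fitDap`
  requires ≥ 10 recordings and at least one varying feature dimension
  (an all-constant matrix is an error naming offending dimensions).
* Test and script problem sizes are chosen to exercise the asymptotics
  cheaply: unit-test cohorts use 20–30 subjects with 1.5–3 h sessions;
  the DAP-recovery and longitudinal checks use a 50-subject default
  cohort (≈ 200 recordings at full session lengths); replicability
  uses 50 replicate cohort pairs of 150 recordings with 1–3 h sessions
  and 400-resample parameter bootstraps; the acceptance script runs the
  full 61-subject default twice plus a 150-subject physical cohort
  (subsampled to motor-cohort scale, as one would subsample a large
  growth database for a like-for-like comparison).

## Known limitations

* The playtime classifier is linear on window distributions; it
  separates the synthetic emission contrast cleanly, but real playtime
  annotation may need richer features or nonlinear boundaries.
* Exact GP regression is O(n³); beyond a few thousand measurements,
  subject-grouped k-fold evaluation and subsampling (as used for the
  physical cohorts) are the intended path, not sparse approximations.
* DAP saturates where the feature trajectory saturates (fluent walking
  near 18 months), so charts should not be extrapolated past the
  configured age range.
* The two-stage LME correction conditions on the fitted mean curve; a
  joint nonlinear mixed model would propagate curve uncertainty into
  the variance components but was deliberately not adopted (see above).
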