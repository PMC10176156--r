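# motorchart

Growth charts for infant gross motor development, built from wearable
posture/movement label streams.

Multisensor wearables can classify an infant's posture (supine, prone,
side, crawl posture, sitting, standing) and movement type (still, proto,
elementary, fluent, pivot, roll, transition) for every couple of seconds
of spontaneous play at home. `motorchart` turns such frame-level label
streams into quantitative developmental measures for clinicians and
researchers studying early neurodevelopment:

1. **Stream processing** — 2.3 s frames with 50% overlap (1.15 s hop),
   removal of low-signal-quality and caregiver-carried frames, and
   automatic free-play ("playtime") detection with a regularized linear
   classifier on overlapping 10-minute window distributions; only
   playtime frames are analysed.
2. **Motor features** — per recording, the posture occupancy distribution
   and the posture-conditioned movement distribution (a fixed 48-vector).
3. **Developmental age prediction (DAP)** — Gaussian process regression
   (RBF kernel + white noise, marginal-likelihood hyperparameters) of
   chronological age on the feature vector. A recording's DAP, in months,
   is the expected age of the motor behaviour it contains; DAP minus age
   reflects individual developmental variation. Evaluation is
   leave-one-subject-out (LOSO), so no infant influences their own
   prediction. The same machinery turns length, weight and head
   circumference (individually or combined) into physical DAP scores, so
   motor and physical growth can be compared on one scale.
4. **Growth charts** — a four-parameter logistic (4PL) mean model
   `f(x) = L + (U − L) / (1 + exp(−k (x − x0)))` of DAP versus age, with
   goodness-of-fit `R²` and `σ` (RMS deviation, months) reported for the
   raw points, monthly-mean points, and after removing per-subject random
   intercepts (restricted-maximum-likelihood mixed model) to account for
   serial recordings; all with percentile-bootstrap 95% CIs.
5. **Variability and tracking** — intra-session measurement noise from
   independent 1-hour playtime epochs (per-epoch SD = pair-difference
   SD / √2), and longitudinal ΔDAP versus measurement interval Δage.
6. **Cohort comparison** — per-category monthly-curve Pearson r and MAE
   (%-points) and chart agreement (parameter CI overlap, age-group DAP
   correlation) between two cohorts.

Because real infant cohorts of this kind are not openly distributable,
the package ships a parametric **synthetic cohort generator** that
emulates the characteristic age-dependent category distributions (supine
declines first, then prone, a transient crawl peak, then rising sitting
and standing; proto → elementary → fluent maturation within postures),
per-subject and per-session developmental offsets, playtime/carried/
low-quality session structure, and monotone physical growth curves with
random intercepts — with ground truth exposed for parameter-recovery
testing. All generator defaults live in
`inst/extdata/synth_defaults.yaml`.

## Worked example

```r
library(motorchart)
cfg <- synthConfig(n_subjects = 30, session_hours_range = c(2, 4), seed = 42)
gen <- generateMotorCohort(cfg)
gen$cohort
#> RecordingSet: 128 recordings, 30 subjects, 386.7 h total
#>   ages 4.1-18.0 months | tags: SYNTH

mfs <- motorFeatureSet(gen$cohort)   # playtime selection + 48-dim features
dim(mfs)
#> [1] 48 85     # 85 recordings kept >= 20 min of playtime

res <- losoCv(mfs, seed = 1, n_restarts = 3)
round(sqrt(mean((res$dap_months - res$age_months)^2)), 2)
#> [1] 1.43      # LOSO RMSE in months

chart <- buildChart(data.frame(age_months = res$age_months,
                               value = res$dap_months,
                               subject_id = res$subject_id),
                    "motor", n_boot = 1000, seed = 1)
chart
#> GrowthChart [motor]: 85 measurements, 27 subjects
#>   4PL: L=3.71 U=16.35 x0=9.83 k=0.350 | band +/- 1.28 months
#>   raw           R2 = 0.889 [0.844, 0.934]  sigma = 1.28 [1.03, 1.44] months
#>   monthly_means R2 = 0.965 [0.895, 0.981]  sigma = 0.64 [0.48, 1.10] months
#>   id_controlled R2 = 0.924 [0.890, 0.964]  sigma = 1.06 [0.75, 1.21] months
```

Read it as a growth chart: the 4PL curve is the population mean DAP
trajectory, the ±1.28-month band is the raw between-recording spread,
monthly averages track the model tightly (R² = 0.97), and accounting for
each infant's own offset (serial recordings) tightens σ from 1.28 to
1.06 months. `runExperiment("all", cfg)` orchestrates the full study
design — replicability between two cohorts, motor versus physical
charts, and longitudinal tracking — and writes all stage tables.

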