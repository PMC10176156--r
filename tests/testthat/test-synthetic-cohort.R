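# The cohort generator: frame-level label model, noise structure,
# determinism, and the physical growth table.

test_that("empirical posture fractions converge to the softmax model", {
  # noiseless, memoryless, playtime-only recording of ~1e5 frames
  age <- 9.5
  cfg <- synthConfig(n_subjects = 1, recordings_per_subject = c(1, 1),
                     age_range = c(age - 1e-9, age + 1e-9),
                     session_hours_range = rep(1e5 / framesPerHour(), 2),
                     playtime_fraction = 1, carried_fraction = 0,
                     lowquality_fraction = 0,
                     sigma_dev = 0, sigma_sess = 0, p_stay = 0, seed = 7)
  rec <- generateMotorCohort(cfg)$cohort[[1]]
  expect_gte(nrow(rec@frames), 99000)
  truth <- modelProbabilities(cfg, rec@ageMonths)
  emp <- table(factor(rec@frames$posture, levels = cfg@postures)) /
    nrow(rec@frames)
  expect_lt(max(abs(as.numeric(emp) - truth$posture)), 0.01)
  # conditional movement distributions converge too
  sit <- rec@frames$movement[rec@frames$posture == "sitting"]
  emp_m <- table(factor(sit, levels = cfg@movements)) / length(sit)
  expect_lt(max(abs(as.numeric(emp_m) - truth$movement["sitting", ])), 0.02)
})

test_that("persistence preserves marginal fractions but adds autocorrelation", {
  age <- 9.5
  base <- list(n_subjects = 1, recordings_per_subject = c(1, 1),
               age_range = c(age - 1e-9, age + 1e-9),
               session_hours_range = rep(5e4 / framesPerHour(), 2),
               playtime_fraction = 1, carried_fraction = 0,
               lowquality_fraction = 0, sigma_dev = 0, sigma_sess = 0)
  cfg <- do.call(synthConfig, c(base, list(p_stay = 0.9, seed = 8)))
  rec <- generateMotorCohort(cfg)$cohort[[1]]
  truth <- modelProbabilities(cfg, age)$posture
  emp <- table(factor(rec@frames$posture, levels = cfg@postures)) /
    nrow(rec@frames)
  expect_lt(max(abs(as.numeric(emp) - truth)), 0.05)
  same <- mean(rec@frames$posture[-1] == rec@frames$posture[-nrow(rec@frames)])
  expect_gt(same, 0.85)   # dwell structure present
})

test_that("degenerate fractions and invalid configs are handled", {
  cfg <- synthConfig(n_subjects = 1, recordings_per_subject = c(1, 1),
                     session_hours_range = c(0.5, 0.5),
                     playtime_fraction = 0, carried_fraction = 0,
                     lowquality_fraction = 1, seed = 3)
  rec <- generateMotorCohort(cfg)$cohort[[1]]
  expect_true(all(!rec@frames$quality_flag))
  expect_warning(out <- applyQualityMask(rec), "no frames")
  expect_equal(nrow(out), 0L)

  expect_error(synthConfig(p_stay = 1), "p_stay")
  expect_error(synthConfig(age_range = c(10, 10)), "age_range")
  expect_error(synthConfig(playtime_fraction = 0.7, carried_fraction = 0.3,
                           lowquality_fraction = 0.2), "<= 1")
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- synthConfig(n_subjects = 3, session_hours_range = c(0.5, 1), seed = 7)
  g1 <- generateMotorCohort(cfg)
  g2 <- generateMotorCohort(cfg)
  expect_identical(manifest(g1$cohort), manifest(g2$cohort))
  for (rid in names(g1$cohort))
    expect_identical(g1$cohort[[rid]]@frames, g2$cohort[[rid]]@frames)
  expect_identical(g1$truth$subject_offsets, g2$truth$subject_offsets)
  p1 <- generatePhysicalCohort(cfg)
  p2 <- generatePhysicalCohort(cfg)
  expect_identical(p1$measurements, p2$measurements)
})

test_that("fluent movement share increases monotonically with maturity", {
  cfg <- synthConfig()
  d <- seq(4, 18, by = 0.5)
  for (p in cfg@postures) {
    fl <- vapply(d, function(x)
      modelProbabilities(cfg, x)$movement[p, "fluent"], numeric(1))
    expect_true(all(diff(fl) > 0), info = p)
  }
})

test_that("physical measurements follow the random-intercept model", {
  # noiseless limit: values equal the median curve exactly
  cfg0 <- synthConfig(n_subjects = 5, seed = 11)
  cfg0@physicalCurves <- lapply(cfg0@physicalCurves, function(cv) {
    cv$sigma_subj <- 0; cv$sigma_meas <- 0; cv
  })
  m0 <- generatePhysicalCohort(cfg0)$measurements
  expect_equal(m0$length_cm, physicalMedian(cfg0, "length", m0$age_months),
               tolerance = 1e-12)
  # variance addition: SD of residuals ~ sqrt(sigma_subj^2 + sigma_meas^2)
  cfg <- synthConfig(n_subjects = 2000, seed = 12)
  m <- generatePhysicalCohort(cfg)$measurements
  res <- m$length_cm - physicalMedian(cfg, "length", m$age_months)
  cv <- cfg@physicalCurves$length
  expect_equal(sd(res), sqrt(cv$sigma_subj^2 + cv$sigma_meas^2),
               tolerance = 0.05)
  # shared intercept: within-subject residuals correlate across visits
  icc <- cv$sigma_subj^2 / (cv$sigma_subj^2 + cv$sigma_meas^2)
  first2 <- do.call(rbind, lapply(split(res, m$subject_id), function(r)
    if (length(r) >= 2) r[1:2]))
  expect_equal(cor(first2[, 1], first2[, 2]), icc, tolerance = 0.1)
  # non-monotone configured curve rejected
  bad <- synthConfig(n_subjects = 5, seed = 1)
  bad@physicalCurves$length$b <- -10
  expect_error(generatePhysicalCohort(bad), "monotone|increasing")
})

test_that("stream files round-trip through the delimited-text interface", {
  gen <- fix_gen()
  dir <- withr::local_tempdir()
  path <- writeCohort(gen$cohort, dir)
  back <- readCohort(path)
  expect_identical(names(back), names(gen$cohort))
  rid <- names(gen$cohort)[3]
  expect_identical(back[[rid]]@frames, gen$cohort[[rid]]@frames)
  expect_equal(back[[rid]]@ageMonths, gen$cohort[[rid]]@ageMonths)
})
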