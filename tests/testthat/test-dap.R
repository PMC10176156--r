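# Gaussian-process developmental age prediction.

test_that("GP predictions agree with an independent linear-algebra oracle", {
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.1)
  m <- fitDap(X, y, seed = 1, n_restarts = 3)
  pr <- predictDap(m, X[1:5, , drop = FALSE])
  # oracle: naive solve() on the same kernel, no Cholesky machinery
  sf2 <- exp(m@hyp[["log_sf2"]]); ell2 <- exp(m@hyp[["log_ell2"]])
  sn2 <- exp(m@hyp[["log_sn2"]])
  Xs <- sweep(sweep(X, 2, m@featCenter), 2, m@featScale, "/")
  D2 <- as.matrix(dist(Xs))^2
  K <- sf2 * exp(-0.5 * D2 / ell2) + diag(sn2 + 1e-10, n)
  ys <- (y - m@yCenter) / m@yScale
  mu <- (sf2 * exp(-0.5 * D2[1:5, ] / ell2)) %*% solve(K, ys)
  expect_equal(pr$dap_months, as.numeric(mu) * m@yScale + m@yCenter,
               tolerance = 1e-8)
})

test_that("GP mean matches kernlab under identical hyperparameters", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  n <- 50
  X <- matrix(rnorm(n * 2), n, 2)
  y <- sin(X[, 1]) + rnorm(n, 0, 0.05)
  ell2 <- 0.8; sn2 <- 0.01
  # my path, with sf2 fixed at 1 to match kernlab's unit-amplitude rbfdot
  D2 <- as.matrix(dist(X))^2
  K <- exp(-0.5 * D2 / ell2) + diag(sn2 + 1e-10, n)
  L <- chol(K)
  fit <- list(theta = c(log_sf2 = 0, log_ell2 = log(ell2),
                        log_sn2 = log(sn2)),
              L = L, alpha = backsolve(L, forwardsolve(t(L), y)))
  mine <- motorchart:::.gp_predict(fit, X, X[1:7, , drop = FALSE])$mean
  kl <- kernlab::gausspr(X, y, type = "regression", kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * ell2)), var = sn2,
                         scaled = FALSE)
  theirs <- as.numeric(kernlab::predict(kl, X[1:7, , drop = FALSE]))
  expect_equal(mine, theirs, tolerance = 1e-6)
})

test_that("degenerate targets and features are handled explicitly", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  constant <- fitDap(X, rep(10, 20), seed = 1)
  pr <- predictDap(constant, X)
  expect_equal(pr$dap_months, rep(10, 20), tolerance = 0.05)
  expect_error(fitDap(matrix(1, 20, 3), rnorm(20)), "constant")
  expect_error(fitDap(X[1:5, ], rnorm(5)), "at least 10")
  expect_error(predictDap(constant, X[, 1:2]), "dimension mismatch")
})

test_that("refitting with the same seed gives identical hyperparameters", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rowSums(X) + rnorm(30, 0, 0.2)
  m1 <- fitDap(X, y, seed = 9, n_restarts = 3)
  m2 <- fitDap(X, y, seed = 9, n_restarts = 3)
  expect_identical(m1@hyp, m2@hyp)
})

test_that("posterior behaves like a GP: interpolation, prior reversion, determinism", {
  set.seed(6)
  X <- matrix(seq(0, 1, length.out = 25), ncol = 1)
  y <- 4 + 10 * X[, 1] + rnorm(25, 0, 0.01)
  m <- fitDap(X, y, seed = 1, n_restarts = 3)
  pr <- predictDap(m, X)
  expect_lt(max(abs(pr$dap_months - y)), 0.15)   # near-noiseless interpolation
  far <- matrix(50, 1, 1)
  pf <- predictDap(m, far)
  expect_gte(pf$predictive_sd_months, max(pr$predictive_sd_months))
  dup <- predictDap(m, rbind(X[3, , drop = FALSE], X[3, , drop = FALSE]))
  expect_equal(dup$dap_months[1], dup$dap_months[2])
  expect_equal(dup$predictive_sd_months[1], dup$predictive_sd_months[2])
})

test_that("LOSO folds never leak subjects and cover every recording", {
  set.seed(7)
  subj <- rep(c("a", "b", "c"), each = 5)
  age <- runif(15, 4, 18)
  X <- cbind(age / 18 + rnorm(15, 0, 0.02))
  rownames(X) <- sprintf("r%02d", 1:15)
  res <- losoCv(X, age, subj, seed = 1, n_restarts = 2)
  expect_equal(nrow(res), 15L)
  expect_identical(res$recording_id, rownames(X))
  # 3 subjects -> exactly 3 fold models
  expect_length(unique(res$model_tag), 3L)
  # fold f's model tag never predicts its own training subject
  for (s in unique(subj))
    expect_length(unique(res$model_tag[res$subject_id == s]), 1L)
  expect_error(losoCv(X, age, rep("a", 15)), "at least 2 subjects")
})

test_that("permuting training ages destroys LOSO performance", {
  mfs <- fix_mfs()
  set.seed(8)
  perm <- losoCv(mfs, ages = sample(ages(mfs)), subjects = subjectIds(mfs),
                 seed = 1, n_restarts = 2)
  r2 <- 1 - sum((perm$dap_months - perm$age_months)^2) /
    sum((perm$age_months - mean(perm$age_months))^2)
  expect_lte(r2, 0.1)
})

test_that("population-mean trajectory maps to monotone DAP", {
  mfs <- fix_mfs()
  model <- fitDap(mfs, seed = 1, n_restarts = 3)
  cfg <- synthConfig()
  grid <- seq(4, 18, by = 0.5)
  traj <- t(vapply(grid, function(d) {
    pr <- modelProbabilities(cfg, d)
    f <- new("MotorFeatures", recordingId = "traj",
             postureFractions = pr$posture,
             conditionalMovement = pr$movement, analysedHours = 1)
    flattenFeatures(f)
  }, numeric(48)))
  dap <- predictDap(model, traj)$dap_months
  expect_true(all(diff(dap) > -0.05))
  expect_gt(dap[length(dap)] - dap[1], 8)   # spans most of the age range
})

test_that("cross-dataset evaluation enforces disjointness and is exchangeable", {
  mkcoh <- function(seed, tag)
    motorFeatureSet(generateMotorCohort(
      synthConfig(n_subjects = 30, recordings_per_subject = c(2, 2),
                  session_hours_range = c(1.5, 3), seed = seed), tag)$cohort)
  A <- mkcoh(41, "SYN-A")
  B <- mkcoh(42, "SYN-B")
  expect_error(crossDatasetEval(A, A), "disjoint")
  cx <- crossDatasetEval(A, B, seed = 1, n_restarts = 3)
  loA <- losoCv(A, seed = 1, n_restarts = 3)
  loB <- losoCv(B, seed = 1, n_restarts = 3)
  cross <- mean(c(rmse(cx$forward), rmse(cx$reverse)))
  within <- mean(c(rmse(loA), rmse(loB)))
  expect_lt(abs(cross - within) / within, 0.2)
  # a noisier test cohort must score worse under the same model
  mknoisy <- function(sess) motorFeatureSet(generateMotorCohort(
    synthConfig(n_subjects = 25, recordings_per_subject = c(2, 2),
                session_hours_range = c(1.5, 3), sigma_sess = sess,
                seed = 77), "SYN-C")$cohort)
  model <- fitDap(A, seed = 1, n_restarts = 3)
  quiet <- mknoisy(0.4); noisy <- mknoisy(1.7)
  rq <- predictDap(model, quiet); rq$age_months <- ages(quiet)
  rn <- predictDap(model, noisy); rn$age_months <- ages(noisy)
  expect_gt(rmse(rn), rmse(rq))
})

test_that("physical DAP respects the generator's information ordering", {
  cfg <- synthConfig(n_subjects = 40, seed = 31)
  cfg0 <- cfg
  cfg0@physicalCurves <- lapply(cfg0@physicalCurves, function(cv) {
    cv$sigma_subj <- 0; cv$sigma_meas <- 0; cv
  })
  m0 <- generatePhysicalCohort(cfg0)$measurements
  p0 <- physicalDap(m0, "length", seed = 1, n_restarts = 2, k = 4)
  r2 <- 1 - sum((p0$dap_months - p0$age_months)^2) /
    sum((p0$age_months - mean(p0$age_months))^2)
  expect_gte(r2, 0.99)      # invertible noiseless growth curve

  meas <- generatePhysicalCohort(cfg)$measurements
  sig <- vapply(c("length", "weight", "hc", "physical3"), function(mod) {
    p <- physicalDap(meas, mod, seed = 1, n_restarts = 2, k = 4)
    f <- fitSigmoid(p$age_months, p$dap_months)
    goodnessOfFit(f, p$age_months, p$dap_months, "raw")$sigma
  }, numeric(1))
  expect_gt(sig[["weight"]], sig[["length"]])  # weight is noisier in months
  expect_lte(sig[["physical3"]], min(sig[c("length", "weight", "hc")]) * 1.1)
})
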