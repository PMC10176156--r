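# 4PL sigmoid fitting, goodness-of-fit groupings, LME correction and
# bootstrap confidence intervals.

test_that("noiseless 4PL points are recovered to high precision", {
  truth <- c(L = 4, U = 18, x0 = 11, k = 0.8)
  x <- seq(4, 18, by = 0.5)
  y <- truth[["L"]] + (truth[["U"]] - truth[["L"]]) /
    (1 + exp(-truth[["k"]] * (x - truth[["x0"]])))
  fit <- fitSigmoid(x, y)
  expect_equal(sigmoidParams(fit), truth, tolerance = 1e-4)
  expect_equal(goodnessOfFit(fit, x, y, "raw")$r2, 1, tolerance = 1e-9)
  # row shuffles cannot change the least-squares optimum
  set.seed(1)
  o <- sample(length(x))
  expect_equal(sigmoidParams(fitSigmoid(x[o], y[o])), sigmoidParams(fit),
               tolerance = 1e-8)
})

test_that("a coarse brute-force grid never beats the optimizer", {
  set.seed(2)
  x <- runif(60, 4, 18)
  y <- 5 + 12 / (1 + exp(-0.6 * (x - 10))) + rnorm(60, 0, 0.7)
  fit <- fitSigmoid(x, y)
  grid_sse <- Inf
  for (L in seq(2, 8, by = 1.5))
    for (U in seq(12, 20, by = 2))
      for (x0 in seq(6, 14, by = 2))
        for (k in c(0.2, 0.4, 0.6, 0.8, 1.2)) {
          sse <- sum((y - (L + (U - L) / (1 + exp(-k * (x - x0)))))^2)
          grid_sse <- min(grid_sse, sse)
        }
  expect_lte(fit@sse, grid_sse + 1e-6)
})

test_that("constant response degenerates gracefully and noisy fits are consistent", {
  x <- seq(4, 18, length.out = 20)
  flat <- fitSigmoid(x, rep(7, 20))
  expect_true(flat@degenerate)
  expect_equal(unname(predict(flat, c(5, 15))), c(7, 7))
  expect_equal(goodnessOfFit(flat, x, rep(7, 20), "raw")$r2, 0)
  expect_error(fitSigmoid(rep(5, 10), rnorm(10)), "all equal")
  # Monte-Carlo consistency: n = 300, sd 0.5 -> curve within 3*sigma/sqrt(n)
  set.seed(3)
  n <- 300; s <- 0.5
  xs <- runif(n, 4, 18)
  ys <- 4 + 14 / (1 + exp(-0.8 * (xs - 11))) + rnorm(n, 0, s)
  f <- fitSigmoid(xs, ys)
  grid <- seq(5, 17, by = 0.5)
  truth <- 4 + 14 / (1 + exp(-0.8 * (grid - 11)))
  expect_lt(max(abs(predict(f, grid) - truth)), 3 * s / sqrt(n) * 4)
})

test_that("goodness-of-fit reproduces hand-computable residual structures", {
  x <- seq(4, 18, length.out = 40)
  y0 <- 4 + 14 / (1 + exp(-0.8 * (x - 11)))
  fit <- fitSigmoid(x, y0)
  q_raw <- goodnessOfFit(fit, x, y0, "raw")
  expect_equal(q_raw$r2, 1, tolerance = 1e-9)
  expect_lt(q_raw$sigma, 1e-4)
  # grouped residuals compare bin-mean values to the curve at bin-mean
  # ages, so a small Jensen gap remains even for exact points
  q_grp <- goodnessOfFit(fit, x, y0, "monthly_means")
  expect_gt(q_grp$r2, 0.999)
  expect_lt(q_grp$sigma, 0.05)
  # alternating +/- 1 residuals have RMS exactly 1 month
  y1 <- y0 + rep(c(1, -1), 20)
  expect_equal(goodnessOfFit(fit, x, y1, "raw")$sigma, 1, tolerance = 1e-12)
  # averaging within bins shrinks noise: grouped R2 >= raw R2
  set.seed(4)
  yn <- y0 + rnorm(40, 0, 1)
  f2 <- fitSigmoid(x, yn)
  expect_gte(goodnessOfFit(f2, x, yn, "monthly_means")$r2,
             goodnessOfFit(f2, x, yn, "raw")$r2)
})

test_that("random-intercept correction recovers variance components", {
  set.seed(5)
  n_sub <- 500
  b <- rnorm(n_sub, 0, 1)
  ids <- rep(sprintf("s%03d", seq_len(n_sub)), each = 4)
  ages <- rep(seq(5, 17, length.out = 4), n_sub)
  flat <- fitSigmoid(seq(4, 18, length.out = 20), rep(0, 20))  # f(x) = 0
  vals <- rep(b, each = 4) + rnorm(4 * n_sub, 0, 0.5)
  lc <- lmeCorrection(ages, vals, ids, flat)
  expect_equal(lc$intercept_sd^2, 1.0, tolerance = 0.15)
  expect_equal(lc$sigma_idcontrolled, 0.5, tolerance = 0.05)
  # pure subject offsets, no within-noise -> corrected sigma ~ 0
  # (lmer warns about the degenerate zero-residual fit; that is the point)
  v0 <- rep(b, each = 4)
  lc0 <- suppressWarnings(lmeCorrection(ages, v0, ids, flat))
  expect_lt(lc0$sigma_idcontrolled, 1e-3)
  # all-singleton subjects fall back to raw residuals with a warning
  expect_warning(
    lmeCorrection(runif(6, 4, 18), rnorm(6), sprintf("u%d", 1:6), flat),
    "repeated")
})

test_that("ID control never increases sigma across seeded cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    n_sub <- 40
    b <- rnorm(n_sub, 0, 1)
    ids <- rep(sprintf("s%02d", seq_len(n_sub)), each = 3)
    ages <- runif(3 * n_sub, 4, 18)
    vals <- 4 + 14 / (1 + exp(-0.8 * (ages - 11))) + rep(b, each = 3) +
      rnorm(3 * n_sub, 0, 0.6)
    fit <- fitSigmoid(ages, vals)
    q_raw <- goodnessOfFit(fit, ages, vals, "raw")
    q_id <- goodnessOfFit(fit, ages, vals, "id_controlled",
                          subject_ids = ids)
    expect_lte(q_id$sigma, q_raw$sigma)
    expect_gte(q_id$r2, q_raw$r2)
  }
})

test_that("bootstrap intervals behave like percentile bootstrap", {
  # constant data: degenerate interval at the point estimate
  bs <- bootstrapCi(function(d) mean(d$x), data.frame(x = rep(5, 4)),
                    n_boot = 200, seed = 1)
  expect_equal(unname(bs$ci[, 1]), c(5, 5))
  # CLT width check: mean of N(0,1), n = 400
  set.seed(6)
  d <- data.frame(x = rnorm(400))
  bs2 <- bootstrapCi(function(dd) mean(dd$x), d, n_boot = 2000, seed = 2)
  width <- unname(bs2$ci["upper", 1] - bs2$ci["lower", 1])
  expect_equal(width, 2 * 1.96 / sqrt(400), tolerance = 0.2)
  bs3 <- bootstrapCi(function(dd) mean(dd$x), d, n_boot = 2000, seed = 2)
  expect_identical(bs2$ci, bs3$ci)
  # subject-unit resampling keeps clusters together
  cl <- data.frame(x = rnorm(30), id = rep(letters[1:10], each = 3))
  bs4 <- bootstrapCi(function(dd) nrow(dd), cl, n_boot = 200,
                     unit = "subject", subject_ids = cl$id, seed = 3)
  expect_equal(unname(bs4$estimate), 30)
})

test_that("chart bundles wire fit, quality, monthly table and span checks together", {
  set.seed(7)
  n_sub <- 45
  b <- rnorm(n_sub, 0, 0.8)
  ids <- rep(sprintf("s%02d", seq_len(n_sub)), each = 3)
  ages <- runif(3 * n_sub, 4, 18)
  vals <- 4 + 14 / (1 + exp(-0.7 * (ages - 11))) + rep(b, each = 3) +
    rnorm(3 * n_sub, 0, 0.5)
  ch <- buildChart(data.frame(age_months = ages, value = vals,
                              subject_id = ids), "motor",
                   n_boot = 300, seed = 1)
  q <- chartQuality(ch)
  expect_setequal(q$grouping, c("raw", "monthly_means", "id_controlled"))
  expect_true(all(q$r2_lo <= q$r2 & q$r2 <= q$r2_hi))
  expect_true(all(q$sigma_lo <= q$sigma & q$sigma <= q$sigma_hi))
  expect_equal(ch@bandSd, q$sigma[q$grouping == "raw"])
  expect_true(all(chartMonthly(ch)$n >= 1))
  ci <- chartParamsCi(ch)
  expect_identical(colnames(ci), c("L", "U", "x0", "k"))
  p <- sigmoidParams(ch)
  expect_true(all(ci["lower", ] <= p & p <= ci["upper", ]))
  expect_error(buildChart(data.frame(age_months = runif(10, 8, 9),
                                     value = rnorm(10),
                                     subject_id = letters[1:10])),
               "insufficient span")
})
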