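# Frame bookkeeping, masking, super-segments and playtime detection.

test_that("frame grid matches the 52 Hz / 2.3 s / 50% overlap bookkeeping", {
  g <- frameGrid(1e6, 52, 2.3, 0.5)
  expect_equal(g$end_sample[1] - g$start_sample[1], 120)
  expect_equal(g$start_sample[2] - g$start_sample[1], 60)
  expect_equal(nrow(frameGrid(100, 52, 2.3, 0.5)), 0L)
  g3 <- frameGrid(240, 52, 2.3, 0.5)
  expect_equal(g3$start_sample, c(0, 60, 120))
  expect_equal(g3$end_sample, c(120, 180, 240))
})

test_that("quality and carried masks count and compose correctly", {
  fr <- toy_frames(1000)
  fr$quality_flag[1:100] <- FALSE
  expect_equal(nrow(applyQualityMask(fr)), 900L)
  clean <- toy_frames(50)
  expect_identical(applyQualityMask(clean), clean)
  expect_identical(applyCarriedMask(clean), clean)
  alt <- toy_frames(100, carried = c(TRUE, FALSE))
  expect_equal(nrow(applyCarriedMask(alt)), 50L)
  expect_equal(nrow(applyCarriedMask(toy_frames(10, carried = TRUE))), 0L)
  # mask composition is order-independent (set intersection)
  fr$carried_flag[50:500] <- TRUE
  expect_identical(applyCarriedMask(applyQualityMask(fr)),
                   applyQualityMask(applyCarriedMask(fr)))
})

test_that("super-segments tile the stream and carry distribution features", {
  s <- superSegments(toy_frames(1040), 520, 0.5)
  expect_equal(s$windows$start_row, c(1L, 261L, 521L))
  expect_false(any(s$windows$short))
  expect_equal(nrow(superSegments(toy_frames(520), 520, 0.5)$windows), 1L)
  short <- superSegments(toy_frames(100), 520, 0.5)
  expect_true(short$windows$short)
  # identical sitting/still frames give a one-hot feature in each block
  f <- s$features[1, ]
  expect_equal(unname(f["posture.sitting"]), 1)
  expect_equal(unname(f["movement.still"]), 1)
  expect_equal(sum(f[startsWith(names(f), "posture.")]), 1)
  expect_equal(sum(f[startsWith(names(f), "movement.")]), 1)
})

test_that("playtime classifier separates, is seeded, and rejects one class", {
  # linearly separable toy windows
  set.seed(1)
  n <- 60
  f <- matrix(runif(n * 4), n, 4,
              dimnames = list(NULL, c("posture.sitting", "posture.supine",
                                      "movement.still", "movement.fluent")))
  lab <- f[, "movement.still"] < 0.5
  f[lab, "movement.still"] <- f[lab, "movement.still"] - 0.4
  m <- trainPlaytimeClassifier(f, lab, seed = 1)
  sc <- detectPlaytime(list(windows = data.frame(start_row = seq_len(n),
                                                 end_row = seq_len(n),
                                                 short = FALSE),
                            features = f), m, n)
  expect_equal(mean(sc$window_positive == lab), 1)
  m2 <- trainPlaytimeClassifier(f, lab, seed = 1)
  expect_identical(m$beta, m2$beta)
  expect_error(trainPlaytimeClassifier(f, rep(TRUE, n)), "single class")
})

test_that("shuffled labels drive balanced cross-validated accuracy to chance", {
  set.seed(10)
  n <- 400
  f <- matrix(runif(n * 6), n, 6,
              dimnames = list(NULL, paste0("posture.", letters[1:6])))
  lab <- rep(c(TRUE, FALSE), n / 2)        # balanced, independent of f
  fold <- rep(1:5, length.out = n)
  acc <- vapply(1:5, function(k) {
    m <- trainPlaytimeClassifier(f[fold != k, ], lab[fold != k], seed = k)
    pred <- detectPlaytime(list(
      windows = data.frame(start_row = seq_len(sum(fold == k)),
                           end_row = seq_len(sum(fold == k)), short = FALSE),
      features = f[fold == k, ]), m, sum(fold == k))$window_positive
    mean(pred == lab[fold == k])
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.1)
})

test_that("window decisions map back to frames by majority with ties positive", {
  # one frame covered by a (+) and a (-) window -> positive
  beta <- setNames(c(10), "posture.sitting")
  model <- structure(list(intercept = -5, beta = beta, lambda = 0,
                          seed = 1L, heldout_accuracy = 1), class = "PlaytimeModel")
  segs <- list(windows = data.frame(start_row = c(1L, 3L),
                                    end_row = c(4L, 6L), short = FALSE),
               features = matrix(c(1, 0), 2, 1,
                                 dimnames = list(NULL, "posture.sitting")))
  pm <- detectPlaytime(segs, model, 6L)
  expect_identical(pm$window_positive, c(TRUE, FALSE))
  expect_true(all(pm$frame_playtime[3:4]))   # tie -> positive
  expect_true(all(pm$frame_playtime[1:2]))
  expect_false(any(pm$frame_playtime[5:6]))
  # all-positive windows -> all frames playtime
  segs$features[] <- 1
  expect_true(all(detectPlaytime(segs, model, 6L)$frame_playtime))
  expect_error(detectPlaytime(segs, list(), 6L), "not been trained")
})

test_that("trained classifier recovers generator playtime on held-out recordings", {
  cfg <- synthConfig(n_subjects = 12, recordings_per_subject = c(2, 2),
                     session_hours_range = c(4, 6), seed = 21)
  gen <- generateMotorCohort(cfg)
  ids <- names(gen$cohort)
  tr <- ids[1:16]; te <- ids[-(1:16)]
  segs <- lapply(tr, function(r)
    superSegments(applyQualityMask(gen$cohort[[r]])))
  model <- trainPlaytimeClassifier(
    do.call(rbind, lapply(segs, `[[`, "features")),
    unlist(lapply(segs, `[[`, "labels")), seed = 1)
  expect_gt(model$heldout_accuracy, 0.9)
  pred <- truth <- logical(0)
  for (r in te) {
    fr <- gen$cohort[[r]]@frames
    q <- which(fr$quality_flag)
    s <- superSegments(fr[q, , drop = FALSE])
    pred <- c(pred, detectPlaytime(s, model, length(q))$frame_playtime)
    truth <- c(truth, fr$playtime_truth[q])
  }
  balanced <- mean(c(mean(pred[truth]), mean(!pred[!truth])))
  expect_gte(balanced, 0.9)
})

test_that("analysis-frame selection applies all masks and the minimum-playtime rule", {
  # fully clean playtime-only hour: retained_hours = 1.0 within one frame
  rec <- toy_recording(toy_frames(framesPerHour()))
  sel <- selectAnalysisFrames(rec, "truth")
  expect_equal(sel$retained_hours, 1.0, tolerance = 1.15 / 3600)
  expect_false(sel$excluded)
  # all carried -> excluded and reported
  relc <- toy_recording(toy_frames(3000, carried = TRUE))
  selc <- selectAnalysisFrames(relc, "truth")
  expect_true(selc$excluded)
  expect_match(selc$reason, "retained")
  expect_equal(nrow(selc$frames), 0L)
  # mask order cannot matter: selection equals the explicit intersection
  gen <- fix_gen()
  r <- gen$cohort[[5]]
  sel2 <- selectAnalysisFrames(r, "truth")
  fr <- r@frames
  expect_identical(sel2$frames,
                   fr[fr$quality_flag & !fr$carried_flag & fr$playtime_truth, ])
  expect_lte(sel2$retained_hours, nrow(fr) * r@hopSeconds / 3600)
  # truth-oracle playtime reduces detection to ground truth (pipeline wiring)
  expect_identical(selectAnalysisFrames(r, fr$playtime_truth)$frames,
                   sel2$frames)
})
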