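# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small default-noise cohort: 20 subjects, shortened sessions
fix_gen <- function() memo("gen", function() {
  cfg <- synthConfig(n_subjects = 20, session_hours_range = c(1.5, 3),
                     seed = 42)
  generateMotorCohort(cfg)
})

fix_mfs <- function() memo("mfs", function() motorFeatureSet(fix_gen()$cohort))

# full-scale cohort under default study conditions (~200 recordings),
# shared by the DAP-recovery and longitudinal-tracking acceptance checks
fix_accept <- function() memo("accept", function() {
  cfg <- synthConfig(n_subjects = 50, seed = 11)
  mfs <- motorFeatureSet(generateMotorCohort(cfg)$cohort)
  list(cfg = cfg, mfs = mfs, loso = losoCv(mfs, seed = 1, n_restarts = 5))
})

# hand-built frame table with full control over the label columns
toy_frames <- function(n, posture = "sitting", movement = "still",
                       carried = FALSE, quality = TRUE, playtime = TRUE) {
  data.frame(frame_index = seq_len(n),
             posture = rep_len(posture, n),
             movement = rep_len(movement, n),
             carried_flag = rep_len(carried, n),
             quality_flag = rep_len(quality, n),
             playtime_truth = rep_len(playtime, n),
             stringsAsFactors = FALSE)
}

toy_recording <- function(frames, id = "rec1", subject = "subj1",
                          age = 10, tag = "TOY", hop = 1.15) {
  new("RecordingSession", recordingId = id, subjectId = subject,
      datasetTag = tag, ageMonths = age, frames = frames, hopSeconds = hop)
}

rmse <- function(d) sqrt(mean((d$dap_months - d$age_months)^2))
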