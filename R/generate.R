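# Synthetic cohort generation.
#
# The generating model: each subject i carries a developmental offset
# delta_i ~ N(0, sigma_dev^2); each recording r adds a situational offset
# eta_r ~ N(0, sigma_sess^2).  During free play at developmental age
# d = age + delta_i + eta_r the per-frame posture is categorical with
# probabilities softmax(z_p(d)) and the movement given posture follows the
# ordinal maturation model (see modelProbabilities).  Sessions are tiled by
# contiguous blocks (geometric lengths, configurable mean) of free play,
# carried, low-quality and other non-play time; consecutive frames repeat
# the previous state with probability p_stay, otherwise the state is
# redrawn.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  expr
}

# categorical draw for n frames, vectorized
.rcat <- function(n, categories, prob) {
  if (n == 0L) return(character(0))
  categories[sample.int(length(categories), n, replace = TRUE, prob = prob)]
}

# contiguous block labels covering n frames; block lengths are geometric
# with a per-type mean, and type draw probabilities are scaled by 1/mean
# length so the expected time share of each type equals type_probs
.block_types <- function(n, mean_frames_by_type, type_probs) {
  keep <- type_probs > 0
  types <- names(type_probs)[keep]
  type_probs <- type_probs[keep]
  means <- mean_frames_by_type[types]
  if (length(types) == 1L) return(rep(types, n))
  draw_probs <- type_probs / means
  mean_draw_len <- sum(draw_probs / sum(draw_probs) * means)
  out <- character(0)
  while (length(out) < n) {
    m <- max(8L, ceiling((n - length(out)) / mean_draw_len) + 4L)
    lab <- .rcat(m, types, draw_probs)
    len <- 1L + rgeom(m, prob = 1 / means[lab])
    out <- c(out, rep(lab, len))
  }
  out[seq_len(n)]
}

# draw a (posture, movement) label sequence with persistence p_stay from a
# fixed emission model: pp over postures, mm[p, ] over movements
.draw_states <- function(n, pp, mm, p_stay) {
  redraw <- c(TRUE, runif(n - 1L) >= p_stay)
  idx <- which(redraw)
  post_new <- .rcat(length(idx), names(pp), pp)
  move_new <- character(length(idx))
  for (p in unique(post_new)) {
    sel <- post_new == p
    move_new[sel] <- .rcat(sum(sel), colnames(mm), mm[p, ])
  }
  f <- findInterval(seq_len(n), idx)
  list(posture = post_new[f], movement = move_new[f])
}

.emission_tables <- function(config, emission) {
  pp <- setNames(rep(0, length(config@postures)), config@postures)
  pp[names(emission$posture)] <- unlist(emission$posture)
  mm <- matrix(0, length(config@postures), length(config@movements),
               dimnames = list(config@postures, config@movements))
  mv <- unlist(emission$movement)
  for (p in config@postures) mm[p, names(mv)] <- mv
  list(pp = pp / sum(pp), mm = mm / rowSums(mm))
}

.simulate_recording <- function(config, rec_id, subj_id, tag, age, d, n_frames) {
  type_probs <- c(play = config@playtimeFraction,
                  carried = config@carriedFraction,
                  lowq = config@lowqualityFraction,
                  nonplay = 1 - config@playtimeFraction - config@carriedFraction -
                    config@lowqualityFraction)
  type_probs[type_probs < 0] <- 0
  to_frames <- function(min) max(1, min * 60 / config@hopSeconds)
  mean_frames <- c(play = to_frames(config@playBlockMinutes),
                   carried = to_frames(config@blockMinutes),
                   lowq = to_frames(config@blockMinutes),
                   nonplay = to_frames(config@playBlockMinutes))
  btype <- .block_types(n_frames, mean_frames, type_probs)

  posture <- character(n_frames)
  movement <- character(n_frames)
  probs <- modelProbabilities(config, d)
  nonplay <- .emission_tables(config, config@nonplayEmission)
  carried <- .emission_tables(config, config@carriedEmission)
  for (ty in unique(btype)) {
    sel <- btype == ty
    ns <- sum(sel)
    st <- switch(ty,
      play = .draw_states(ns, probs$posture, probs$movement, config@pStay),
      nonplay = .draw_states(ns, nonplay$pp, nonplay$mm, config@pStay),
      carried = .draw_states(ns, carried$pp, carried$mm, config@pStay),
      lowq = list(posture = .rcat(ns, config@postures, NULL),
                  movement = .rcat(ns, config@movements, NULL)))
    posture[sel] <- st$posture
    movement[sel] <- st$movement
  }
  frames <- data.frame(
    frame_index = seq_len(n_frames),
    posture = posture,
    movement = movement,
    carried_flag = btype == "carried",
    quality_flag = btype != "lowq",
    playtime_truth = btype == "play",
    stringsAsFactors = FALSE)
  new("RecordingSession", recordingId = rec_id, subjectId = subj_id,
      datasetTag = tag, ageMonths = age, frames = frames,
      hopSeconds = config@hopSeconds)
}

#' Generate a synthetic motor-label cohort
#'
#' Simulates frame-level posture/movement/carried/quality label streams for
#' a cohort of infants under the generating model of a [SynthConfig-class],
#' together with the latent ground truth (per-subject and per-session
#' developmental offsets) used by parameter-recovery tests.  The same
#' configuration (including its seed) always reproduces the same cohort.
#'
#' @param config a [SynthConfig-class].
#' @param dataset_tag dataset label stamped on every recording.
#' @return a list with elements `cohort` (a [RecordingSet-class]) and
#'   `truth` (list with `subject_offsets`, `session_offsets`, and the
#'   generating `config`).
#' @examples
#' cfg <- synthConfig(n_subjects = 3, session_hours_range = c(0.5, 0.5), seed = 7)
#' gen <- generateMotorCohort(cfg)
#' manifest(gen$cohort)
#' @export
generateMotorCohort <- function(config, dataset_tag = "SYNTH") {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  .with_seed(config@seed, {
    fph <- framesPerHour(config@hopSeconds)
    recs <- list()
    subject_offsets <- numeric(0)
    session_offsets <- numeric(0)
    for (i in seq_len(config@nSubjects)) {
      subj <- sprintf("%s-S%03d", dataset_tag, i)
      delta <- rnorm(1, 0, config@sigmaDev)
      subject_offsets[subj] <- delta
      k <- sample(seq(config@recordingsPerSubject[1],
                      config@recordingsPerSubject[2]), 1L)
      rec_ages <- sort(runif(k, config@ageRange[1], config@ageRange[2]))
      for (j in seq_len(k)) {
        rid <- sprintf("%s-R%02d", subj, j)
        eta <- rnorm(1, 0, config@sigmaSess)
        session_offsets[rid] <- eta
        hours <- runif(1, config@sessionHoursRange[1], config@sessionHoursRange[2])
        n_frames <- max(1L, as.integer(floor(hours * fph)))
        d <- rec_ages[j] + delta + eta
        recs[[rid]] <- .simulate_recording(config, rid, subj, dataset_tag,
                                           rec_ages[j], d, n_frames)
      }
    }
    list(cohort = new("RecordingSet", recordings = recs),
         truth = list(subject_offsets = subject_offsets,
                      session_offsets = session_offsets,
                      config = config))
  })
}

#' Evaluate a configured physical median curve
#'
#' @param config a [SynthConfig-class].
#' @param modality `"length"`, `"weight"` or `"hc"`.
#' @param t age in months (vectorized).
#' @return median measurement values `a + b (1 - exp(-t / tau))`.
#' @export
physicalMedian <- function(config, modality, t) {
  cv <- config@physicalCurves[[modality]]
  if (is.null(cv)) stop("unknown modality: ", modality)
  cv$a + cv$b * (1 - exp(-t / cv$tau))
}

#' Generate a synthetic physical growth table
#'
#' Simulates serial length/weight/head-circumference measurements on a
#' clinic visit schedule: `m_ij = mu_k(t_ij) + b_i + e_ij` with a strictly
#' increasing parametric median curve `mu_k` per modality, subject random
#' intercepts `b_i` and measurement error `e_ij`.
#'
#' @param config a [SynthConfig-class]; `n_subjects`, `age_range` and seed
#'   are taken from it.
#' @return list with `measurements` (`data.frame`: `subject_id`,
#'   `age_months`, `length_cm`, `weight_kg`, `hc_cm`) and `truth`
#'   (per-modality subject intercepts and the generating curve parameters).
#' @examples
#' cfg <- synthConfig(n_subjects = 4, seed = 2)
#' head(generatePhysicalCohort(cfg)$measurements)
#' @export
generatePhysicalCohort <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  modalities <- c(length = "length_cm", weight = "weight_kg", hc = "hc_cm")
  tgrid <- seq(config@ageRange[1], config@ageRange[2], length.out = 200)
  for (k in names(modalities)) {
    mu <- physicalMedian(config, k, tgrid)
    if (any(diff(mu) <= 0))
      stop("configured median curve for '", k, "' is not strictly increasing")
  }
  .with_seed(config@seed + 1L, {
    vis <- config@physicalVisits
    sched <- unlist(vis$schedule_months)
    sched <- sched[sched >= config@ageRange[1] & sched <= config@ageRange[2]]
    rows <- vector("list", config@nSubjects)
    intercepts <- lapply(modalities, function(m) numeric(config@nSubjects))
    for (i in seq_len(config@nSubjects)) {
      subj <- sprintf("P%05d", i)
      attend <- runif(length(sched)) < vis$attend_prob
      if (!any(attend)) attend[sample.int(length(sched), 1L)] <- TRUE
      t_i <- sort(pmin(pmax(sched[attend] + rnorm(sum(attend), 0, vis$jitter_sd_months),
                            config@ageRange[1]), config@ageRange[2]))
      df <- data.frame(subject_id = subj, age_months = t_i,
                       stringsAsFactors = FALSE)
      for (k in names(modalities)) {
        cv <- config@physicalCurves[[k]]
        b <- rnorm(1, 0, cv$sigma_subj)
        intercepts[[k]][i] <- b
        df[[modalities[[k]]]] <- physicalMedian(config, k, t_i) + b +
          rnorm(length(t_i), 0, cv$sigma_meas)
      }
      rows[[i]] <- df
    }
    for (k in names(modalities))
      names(intercepts[[k]]) <- sprintf("P%05d", seq_len(config@nSubjects))
    list(measurements = do.call(rbind, rows),
         truth = list(subject_intercepts = intercepts,
                      curves = config@physicalCurves))
  })
}
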