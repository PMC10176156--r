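#' Build a synthetic-cohort configuration
#'
#' Constructs a [SynthConfig-class] from the packaged defaults file
#' (`inst/extdata/synth_defaults.yaml`), optionally overriding individual
#' parameters.  The defaults emulate a home-recorded infant cohort between
#' 4 and 18 months of age: session lengths of 1.4-14.2 h, roughly a quarter
#' of the time in free play, a per-subject developmental offset of 1 month
#' SD and a per-session situational offset of 0.85 months SD.
#'
#' @param n_subjects number of subjects.
#' @param age_range age interval in months, `c(lo, hi)`.
#' @param recordings_per_subject discrete-uniform range `c(lo, hi)`.
#' @param session_hours_range continuous-uniform range of session lengths.
#' @param playtime_fraction,carried_fraction,lowquality_fraction expected
#'   fractions of session time in each state; must sum to at most 1.
#' @param sigma_dev,sigma_sess developmental / situational offset SDs (months).
#' @param p_stay frame-to-frame persistence probability in `[0, 1)`.
#' @param block_minutes mean block length for carried/low-quality
#'   interruptions.
#' @param play_block_minutes mean block length for free-play and other
#'   awake periods.
#' @param seed integer seed.
#' @param defaults_file path to a YAML defaults document; the packaged file
#'   is used when `NULL`.
#' @return a validated [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(n_subjects = 5, seed = 1)
#' cfg
#' @export
synthConfig <- function(n_subjects = NULL, age_range = NULL,
                        recordings_per_subject = NULL,
                        session_hours_range = NULL,
                        playtime_fraction = NULL, carried_fraction = NULL,
                        lowquality_fraction = NULL,
                        sigma_dev = NULL, sigma_sess = NULL, p_stay = NULL,
                        block_minutes = NULL, play_block_minutes = NULL,
                        seed = 1L, defaults_file = NULL) {
  if (is.null(defaults_file))
    defaults_file <- system.file("extdata", "synth_defaults.yaml",
                                 package = "motorchart", mustWork = TRUE)
  def <- yaml::read_yaml(defaults_file)
  co <- def$cohort
  pick <- function(override, default) if (is.null(override)) default else override
  age_range <- as.numeric(pick(age_range, co$age_range_months))
  if (length(age_range) != 2L || diff(age_range) <= 0)
    stop("age_range must be a non-empty interval c(lo, hi)")
  p_stay <- pick(p_stay, co$p_stay)
  if (p_stay >= 1) stop("p_stay must be < 1")
  new("SynthConfig",
      nSubjects = as.integer(pick(n_subjects, co$n_subjects)),
      ageRange = age_range,
      recordingsPerSubject = as.integer(pick(recordings_per_subject,
                                             co$recordings_per_subject)),
      sessionHoursRange = as.numeric(pick(session_hours_range,
                                          co$session_hours_range)),
      playtimeFraction = pick(playtime_fraction, co$playtime_fraction),
      carriedFraction = pick(carried_fraction, co$carried_fraction),
      lowqualityFraction = pick(lowquality_fraction, co$lowquality_fraction),
      sigmaDev = pick(sigma_dev, co$sigma_dev),
      sigmaSess = pick(sigma_sess, co$sigma_sess),
      pStay = p_stay,
      blockMinutes = pick(block_minutes, co$block_minutes),
      playBlockMinutes = pick(play_block_minutes, co$play_block_minutes),
      hopSeconds = co$hop_seconds,
      postures = unlist(def$categories$postures),
      movements = unlist(def$categories$movements),
      trajectories = def$posture_trajectories,
      maturation = def$movement_maturation,
      nonplayEmission = def$nonplay_emission,
      carriedEmission = def$carried_emission,
      physicalCurves = def$physical_curves,
      physicalVisits = def$physical_visits,
      seed = as.integer(seed))
}

#' Frames per hour at a given hop
#'
#' One hour of 1.15-s hops is 3130 frames (floor of 3600/1.15).
#'
#' @param hop_seconds frame hop in seconds.
#' @return integer frame count per hour.
#' @export
framesPerHour <- function(hop_seconds = 1.15) as.integer(floor(3600 / hop_seconds))

#' Model posture/movement probabilities at a developmental age
#'
#' Evaluates the generating model of a configuration: posture probabilities
#' `softmax(z_p(d))` with logistic-in-age logits, and the per-posture
#' movement distributions from the ordinal maturation model.  Used both by
#' the generator and, as the ground-truth oracle, by tests that compare
#' empirical category fractions with the model.
#'
#' @param config a [SynthConfig-class].
#' @param d developmental age in months (scalar).
#' @return list with `posture` (named probability vector) and `movement`
#'   (posture x movement probability matrix, rows summing to 1).
#' @export
modelProbabilities <- function(config, d) {
  stopifnot(is(config, "SynthConfig"), length(d) == 1L, is.finite(d))
  z <- vapply(config@trajectories[config@postures], function(p)
    p$base + p$amp * plogis((d - p$mid) / p$scale), numeric(1))
  ez <- exp(z - max(z))
  posture <- ez / sum(ez)
  names(posture) <- config@postures
  mat <- config@maturation
  th <- unlist(mat$thresholds)  # increasing cuts below proto/elementary/fluent
  movement <- matrix(0, length(config@postures), length(config@movements),
                     dimnames = list(config@postures, config@movements))
  for (p in config@postures) {
    u <- (d - mat$onset[[p]]) / mat$rate[[p]]
    cum <- plogis(th - u)
    ordinal <- c(cum[1], cum[2] - cum[1], cum[3] - cum[2], 1 - cum[3])
    extras <- unlist(mat$extras[[p]])
    if (is.null(extras)) extras <- numeric(0)
    movement[p, c("still", "proto", "elementary", "fluent")] <-
      ordinal * (1 - sum(extras))
    movement[p, names(extras)] <- extras
  }
  list(posture = posture, movement = movement)
}
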