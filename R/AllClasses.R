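#' @import methods
#' @importFrom stats plogis rnorm runif sd var cor cor.test ks.test median
#'   quantile optim predict rgeom coef resid setNames ave
#' @importFrom utils head read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Synthetic cohort generator configuration
#'
#' Full parameterization of the synthetic motor / physical-growth cohort
#' generator: cohort sampling plan, noise components, frame-level emission
#' model and physical growth curves.  Construct with [synthConfig()], which
#' fills every slot from the packaged defaults file
#' (`system.file("extdata", "synth_defaults.yaml", package = "motorchart")`).
#'
#' @slot nSubjects number of subjects.
#' @slot ageRange closed age interval in months, recordings are drawn inside it.
#' @slot recordingsPerSubject discrete-uniform range for recordings per subject.
#' @slot sessionHoursRange continuous-uniform range of session lengths (hours).
#' @slot playtimeFraction,carriedFraction,lowqualityFraction expected fractions
#'   of session time in free play, carried and low-signal-quality states; the
#'   remainder is awake non-play time.
#' @slot sigmaDev per-subject developmental offset SD (months).
#' @slot sigmaSess per-session situational offset SD (months).
#' @slot pStay frame-to-frame persistence probability in `[0, 1)`.
#' @slot blockMinutes mean block length for carried/low-quality interruptions.
#' @slot playBlockMinutes mean block length for free-play and other awake
#'   periods.
#' @slot hopSeconds frame hop in seconds (1.15 s; one hour = 3130 frames).
#' @slot postures,movements category inventories.
#' @slot trajectories per-posture logistic logit parameters (base, amp, mid, scale).
#' @slot maturation ordinal movement-maturation parameters (thresholds, onset,
#'   rate, extras).
#' @slot nonplayEmission,carriedEmission fixed emission distributions outside
#'   free play.
#' @slot physicalCurves per-modality median-curve and noise parameters.
#' @slot physicalVisits visit schedule for physical growth sampling.
#' @slot seed integer seed; the same seed reproduces the cohort exactly.
#' @seealso [synthConfig()], [generateMotorCohort()], [generatePhysicalCohort()]
#' @export
setClass("SynthConfig", representation(
  nSubjects = "integer",
  ageRange = "numeric",
  recordingsPerSubject = "integer",
  sessionHoursRange = "numeric",
  playtimeFraction = "numeric",
  carriedFraction = "numeric",
  lowqualityFraction = "numeric",
  sigmaDev = "numeric",
  sigmaSess = "numeric",
  pStay = "numeric",
  blockMinutes = "numeric",
  playBlockMinutes = "numeric",
  hopSeconds = "numeric",
  postures = "character",
  movements = "character",
  trajectories = "list",
  maturation = "list",
  nonplayEmission = "list",
  carriedEmission = "list",
  physicalCurves = "list",
  physicalVisits = "list",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  fr <- object@playtimeFraction + object@carriedFraction + object@lowqualityFraction
  if (fr > 1 + 1e-12)
    msg <- c(msg, "playtimeFraction + carriedFraction + lowqualityFraction must be <= 1")
  if (any(c(object@sigmaDev, object@sigmaSess) < 0))
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@ageRange[1] < 0 || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be a non-empty interval with lower bound >= 0")
  if (object@pStay < 0 || object@pStay >= 1)
    msg <- c(msg, "pStay must lie in [0, 1)")
  if (object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be >= 1")
  if (object@hopSeconds <= 0)
    msg <- c(msg, "hopSeconds must be > 0")
  if (!all(object@postures %in% names(object@trajectories)))
    msg <- c(msg, "every posture needs a trajectory entry")
  if (length(msg)) msg else TRUE
})

#' One wearable recording session of frame-level labels
#'
#' Frame-level classifier outputs for one recording: per-frame posture,
#' movement, carried flag, signal-quality flag and (for synthetic data) the
#' ground-truth playtime flag, together with subject/session metadata.
#'
#' @slot recordingId,subjectId,datasetTag identifiers.
#' @slot ageMonths chronological age at the recording, real-valued months.
#' @slot frames `data.frame` with columns `frame_index`, `posture`,
#'   `movement`, `carried_flag`, `quality_flag` (`TRUE` = usable) and
#'   optionally `playtime_truth`.
#' @slot hopSeconds frame hop in seconds.
#' @export
setClass("RecordingSession", representation(
  recordingId = "character",
  subjectId = "character",
  datasetTag = "character",
  ageMonths = "numeric",
  frames = "data.frame",
  hopSeconds = "numeric"
))

setValidity("RecordingSession", function(object) {
  msg <- character()
  fr <- object@frames
  need <- c("frame_index", "posture", "movement", "carried_flag", "quality_flag")
  if (!all(need %in% names(fr)))
    msg <- c(msg, paste("frames must contain columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(fr) == 0L) msg <- c(msg, "frames must be non-empty")
    else if (any(diff(fr$frame_index) <= 0))
      msg <- c(msg, "frame_index must be strictly increasing")
  }
  if (length(object@ageMonths) != 1L || is.na(object@ageMonths) || object@ageMonths < 0)
    msg <- c(msg, "ageMonths must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' A cohort of recording sessions
#'
#' A list-like container of [RecordingSession-class] objects with a cohort
#' manifest.  Returned by [generateMotorCohort()] and [readCohort()].
#'
#' @slot recordings list of `RecordingSession` objects, named by recording id.
#' @export
setClass("RecordingSet", representation(recordings = "list"))

setValidity("RecordingSet", function(object) {
  ok <- vapply(object@recordings, is, logical(1), class2 = "RecordingSession")
  if (!all(ok)) return("all elements must be RecordingSession objects")
  ids <- vapply(object@recordings, function(r) r@recordingId, character(1))
  if (anyDuplicated(ids)) return("recording ids must be unique")
  TRUE
})

#' Motor feature distributions of one recording
#'
#' The DAP feature representation of a single recording: the posture
#' occupancy distribution and, for each posture, the distribution of
#' movement categories among the frames spent in that posture.  Postures
#' never observed get an all-zero conditional row, keeping the feature
#' space fixed-dimensional.
#'
#' @slot recordingId recording identifier.
#' @slot postureFractions named vector over postures, sums to 1.
#' @slot conditionalMovement posture x movement matrix; each nonzero row
#'   sums to 1.
#' @slot analysedHours playtime hours behind the distributions.
#' @export
setClass("MotorFeatures", representation(
  recordingId = "character",
  postureFractions = "numeric",
  conditionalMovement = "matrix",
  analysedHours = "numeric"
))

setValidity("MotorFeatures", function(object) {
  msg <- character()
  pf <- object@postureFractions
  cm <- object@conditionalMovement
  if (any(pf < -1e-12) || any(pf > 1 + 1e-12) || abs(sum(pf) - 1) > 1e-9)
    msg <- c(msg, "postureFractions must lie in [0,1] and sum to 1")
  if (!identical(rownames(cm), names(pf)))
    msg <- c(msg, "conditionalMovement rows must match postureFractions names")
  rs <- rowSums(cm)
  if (any(rs > 1e-12 & abs(rs - 1) > 1e-9))
    msg <- c(msg, "each nonzero conditional row must sum to 1")
  if (any(cm < -1e-12 | cm > 1 + 1e-12))
    msg <- c(msg, "conditional entries must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Recording-level motor feature container
#'
#' A \linkS4class{SummarizedExperiment} whose single assay `"fraction"` holds
#' the flattened DAP feature vectors, one column per recording: the posture
#' occupancy fractions followed by the row-major posture-conditioned movement
#' distribution.  `rowData` identifies each feature cell (type, posture,
#' movement); `colData` carries the manifest (subject, dataset tag, age,
#' analysed hours).
#'
#' @export
setClass("MotorFeatureSet", contains = "SummarizedExperiment")

#' Gaussian-process developmental age prediction model
#'
#' A fitted features-to-age Gaussian process regression (radial basis
#' function kernel plus white noise), the machinery behind DAP.  Hyper-
#' parameters are chosen by marginal-likelihood maximization over seeded
#' restarts; features and the age target are standardized internally.
#'
#' @slot X standardized training feature matrix (recordings x features).
#' @slot hyp named log-hyperparameters `log_sf2`, `log_ell2`, `log_sn2`.
#' @slot alpha weight vector `K^{-1} y` on the standardized scale.
#' @slot L lower Cholesky factor of the training kernel matrix.
#' @slot featCenter,featScale,yCenter,yScale standardization statistics.
#' @slot trainingManifest `data.frame` of recording and subject ids used in
#'   training.
#' @slot seed integer seed used for the optimizer restarts.
#' @slot tag model identity label (training-set identity).
#' @export
setClass("DapModel", representation(
  X = "matrix",
  hyp = "numeric",
  alpha = "numeric",
  L = "matrix",
  featCenter = "numeric",
  featScale = "numeric",
  yCenter = "numeric",
  yScale = "numeric",
  trainingManifest = "data.frame",
  seed = "integer",
  tag = "character"
))

setValidity("DapModel", function(object) {
  msg <- character()
  if (!all(c("log_sf2", "log_ell2", "log_sn2") %in% names(object@hyp)))
    msg <- c(msg, "hyp must contain log_sf2, log_ell2, log_sn2")
  else if (exp(object@hyp[["log_sn2"]]) <= 0)
    msg <- c(msg, "noise variance must be > 0")
  if (nrow(object@trainingManifest) == 0L)
    msg <- c(msg, "training manifest must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic (4PL) sigmoid fit
#'
#' Least-squares fit of `f(x) = L + (U - L) / (1 + exp(-k (x - x0)))`.
#'
#' @slot params named numeric `(L, U, x0, k)`.
#' @slot sse residual sum of squares at the optimum.
#' @slot converged whether at least one start converged.
#' @slot degenerate `TRUE` when the response had (near-)zero variance and a
#'   flat curve was returned.
#' @slot n number of points fitted.
#' @export
setClass("SigmoidFit", representation(
  params = "numeric", sse = "numeric", converged = "logical",
  degenerate = "logical", n = "integer"
))

setValidity("SigmoidFit", function(object) {
  p <- object@params
  if (!all(c("L", "U", "x0", "k") %in% names(p)))
    return("params must be named L, U, x0, k")
  if (p[["U"]] < p[["L"]] - 1e-9) return("U must be >= L")
  if (!is.finite(p[["k"]])) return("k must be finite")
  TRUE
})

#' Growth chart bundle
#'
#' A growth chart for one measurement modality: the 4PL mean model of DAP
#' versus age, goodness-of-fit at the raw / monthly-mean / ID-controlled
#' levels with bootstrap confidence intervals, a monthly mean/SD table and
#' the +/- 1 SD band half-width.
#'
#' @slot modality modality tag, e.g. `"motor"`, `"length"`, `"physical3"`.
#' @slot fit the [SigmoidFit-class] mean model.
#' @slot quality `data.frame` of R-squared and sigma (months) per grouping
#'   level with 95% CIs.
#' @slot monthly monthly mean/SD/count table.
#' @slot data the chart points (age, value, subject id).
#' @slot bandSd half-width of the plotted +/- 1 SD band (`sigma_raw`, months).
#' @export
setClass("GrowthChart", representation(
  modality = "character", fit = "SigmoidFit", quality = "data.frame",
  monthly = "data.frame", data = "data.frame", bandSd = "numeric"
))

#' Intra-session DAP measurement-noise estimate
#'
#' Variability of DAP scores between independent 1-hour playtime epochs of
#' the same recording session.  The per-epoch noise SD is the SD of the
#' epoch-pair differences divided by `sqrt(2)` (two independent equal-
#' variance epochs).
#'
#' @slot pairs `data.frame` of epoch pairs (recording, epochs, DAP
#'   difference, age).
#' @slot sigmaNoise per-epoch noise SD in months.
#' @slot ksP one-sample Kolmogorov-Smirnov p-value of the standardized
#'   differences against the standard normal.
#' @slot ageCorrR,ageCorrP Pearson correlation of the absolute differences
#'   with age and its p-value.
#' @slot nPairs number of epoch pairs.
#' @export
setClass("NoiseEstimate", representation(
  pairs = "data.frame", sigmaNoise = "numeric", ksP = "numeric",
  ageCorrR = "numeric", ageCorrP = "numeric", nPairs = "integer"
))

setValidity("NoiseEstimate", function(object) {
  if (object@nPairs != nrow(object@pairs)) return("nPairs must match the pair table")
  if (object@sigmaNoise < 0) return("sigmaNoise must be >= 0")
  TRUE
})
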