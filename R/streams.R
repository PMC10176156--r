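# Stream processing: frame bookkeeping, masking, super-segments and
# playtime detection.

.default_categories <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      def <- yaml::read_yaml(system.file("extdata", "synth_defaults.yaml",
                                         package = "motorchart", mustWork = TRUE))
      cache <<- list(postures = unlist(def$categories$postures),
                     movements = unlist(def$categories$movements))
    }
    cache
  }
})

#' Overlapping frame grid over a sample stream
#'
#' Segments `n_samples` IMU samples into fixed-length frames with fractional
#' overlap.  At the standard settings (52 Hz, 2.3 s frames, 50% overlap)
#' frames are 120 samples long with a 60-sample (1.15 s) hop.  Frames tile
#' the stream maximally; a partial trailing frame is discarded.
#'
#' @param n_samples number of samples in the stream.
#' @param rate_hz sampling rate (> 0).
#' @param frame_seconds frame length in seconds.
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @return `data.frame` with 0-based `start_sample` and exclusive
#'   `end_sample` per frame; zero rows when the stream is shorter than one
#'   frame.
#' @examples
#' frameGrid(240, 52, 2.3, 0.5)
#' @export
frameGrid <- function(n_samples, rate_hz = 52, frame_seconds = 2.3,
                      overlap_fraction = 0.5) {
  stopifnot(rate_hz > 0, overlap_fraction >= 0, overlap_fraction < 1,
            n_samples >= 0)
  flen <- as.integer(round(frame_seconds * rate_hz))
  hop <- as.integer(round(flen * (1 - overlap_fraction)))
  if (n_samples < flen)
    return(data.frame(start_sample = integer(0), end_sample = integer(0)))
  starts <- seq.int(0L, as.integer(n_samples) - flen, by = hop)
  data.frame(start_sample = starts, end_sample = starts + flen)
}

.frames_of <- function(x) {
  if (is(x, "RecordingSession")) x@frames
  else if (is.data.frame(x)) x
  else stop("expected a RecordingSession or a frame data.frame")
}

#' Remove low-signal-quality frames
#'
#' @param x a [RecordingSession-class] or frame `data.frame`.
#' @return the frames with `quality_flag == TRUE`; warns when nothing is
#'   retained.
#' @export
applyQualityMask <- function(x) {
  fr <- .frames_of(x)
  out <- fr[fr$quality_flag, , drop = FALSE]
  if (nrow(out) == 0L) warning("no frames pass the quality mask")
  out
}

#' Remove caregiver-carried frames
#'
#' @param x a [RecordingSession-class] or frame `data.frame`.
#' @return the frames with `carried_flag == FALSE`.
#' @export
applyCarriedMask <- function(x) {
  fr <- .frames_of(x)
  fr[!fr$carried_flag, , drop = FALSE]
}

#' Overlapping super-segments with category-distribution features
#'
#' Accumulates frame-level classifications into 10-minute (520-frame)
#' windows with 50% overlap.  Each window's feature vector is the empirical
#' distribution over posture categories followed by the distribution over
#' movement categories (each block summing to 1).  When `playtime_truth` is
#' present, a per-window label (majority truth) is attached for classifier
#' training.
#'
#' @param x a [RecordingSession-class] or frame `data.frame`.
#' @param window_frames window length in frames (>= 1).
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @param postures,movements category inventories; packaged defaults when `NULL`.
#' @return list with `windows` (`data.frame`: 1-based `start_row`,
#'   `end_row`, `short` flag), `features` (windows x categories matrix) and
#'   `labels` (logical or `NULL`).
#' @export
superSegments <- function(x, window_frames = 520L, overlap_fraction = 0.5,
                          postures = NULL, movements = NULL) {
  fr <- .frames_of(x)
  stopifnot(window_frames >= 1)
  cats <- .default_categories()
  if (is.null(postures)) postures <- cats$postures
  if (is.null(movements)) movements <- cats$movements
  n <- nrow(fr)
  hop <- max(1L, as.integer(round(window_frames * (1 - overlap_fraction))))
  if (n < window_frames) {
    win <- data.frame(start_row = 1L, end_row = n, short = TRUE)
  } else {
    starts <- seq.int(1L, n - as.integer(window_frames) + 1L, by = hop)
    win <- data.frame(start_row = starts,
                      end_row = starts + as.integer(window_frames) - 1L,
                      short = FALSE)
  }
  feat <- matrix(0, nrow(win), length(postures) + length(movements),
                 dimnames = list(NULL, c(paste0("posture.", postures),
                                         paste0("movement.", movements))))
  labels <- if ("playtime_truth" %in% names(fr)) logical(nrow(win)) else NULL
  for (w in seq_len(nrow(win))) {
    rows <- win$start_row[w]:win$end_row[w]
    pt <- table(factor(fr$posture[rows], levels = postures))
    mt <- table(factor(fr$movement[rows], levels = movements))
    feat[w, ] <- c(pt / sum(pt), mt / sum(mt))
    if (!is.null(labels)) labels[w] <- mean(fr$playtime_truth[rows]) > 0.5
  }
  list(windows = win, features = feat, labels = labels)
}

#' Train the binary playtime classifier
#'
#' Fits a regularized (ridge) binary logistic-regression classifier on
#' super-segment category-distribution features, distinguishing free-play
#' windows from carried/non-play windows.  A seeded 80/20 split reports
#' held-out accuracy.  Refitting with the same seed gives identical weights.
#'
#' @param features windows x categories feature matrix (see
#'   [superSegments()]).
#' @param labels logical (or 0/1) per-window playtime labels; both classes
#'   must be present.
#' @param seed integer seed for the held-out split.
#' @param lambda ridge penalty.
#' @return a `PlaytimeModel` list: `intercept`, `beta`, `lambda`,
#'   `heldout_accuracy`, `seed`.
#' @export
trainPlaytimeClassifier <- function(features, labels, seed = 1L, lambda = 1e-2) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  stopifnot(nrow(features) == length(labels))
  fit <- glmnet::glmnet(features, factor(labels), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  beta <- as.numeric(fit$beta[, 1])
  names(beta) <- rownames(fit$beta)
  model <- structure(list(intercept = as.numeric(fit$a0), beta = beta,
                          lambda = lambda, seed = as.integer(seed),
                          heldout_accuracy = NA_real_),
                     class = "PlaytimeModel")
  ho <- .with_seed(seed, sample.int(length(labels), max(1L, floor(0.2 * length(labels)))))
  if (length(unique(labels[-ho])) == 2L) {
    refit <- glmnet::glmnet(features[-ho, , drop = FALSE],
                            factor(labels[-ho]), family = "binomial",
                            alpha = 0, lambda = lambda, standardize = FALSE)
    pred <- .playtime_scores(list(intercept = as.numeric(refit$a0),
                                  beta = setNames(as.numeric(refit$beta[, 1]),
                                                  rownames(refit$beta))),
                             features[ho, , drop = FALSE]) > 0
    model$heldout_accuracy <- mean(pred == labels[ho])
  }
  model
}

.playtime_scores <- function(model, features) {
  drop(features[, names(model$beta), drop = FALSE] %*% model$beta) + model$intercept
}

#' Classify playtime and map window decisions back to frames
#'
#' Scores each super-segment with a trained [trainPlaytimeClassifier()]
#' model and back-maps the window decisions: a frame is playtime iff the
#' majority of the windows covering it are positive, with ties counted as
#' positive.  Frames past the last window inherit its decision.
#'
#' @param segments output of [superSegments()].
#' @param model a `PlaytimeModel`.
#' @param n_frames number of frames in the underlying frame set.
#' @param hop_seconds frame hop, used for `retained_hours`.
#' @return list (`PlaytimeMask`): `frame_playtime` logical of length
#'   `n_frames`, `window_positive` per window, `retained_hours`.
#' @export
detectPlaytime <- function(segments, model, n_frames, hop_seconds = 1.15) {
  if (!inherits(model, "PlaytimeModel"))
    stop("playtime classifier has not been trained")
  pos <- .playtime_scores(model, segments$features) > 0
  win <- segments$windows
  npos <- nneg <- numeric(n_frames + 1L)
  for (w in seq_len(nrow(win))) {
    a <- win$start_row[w]; b <- min(win$end_row[w], n_frames)
    if (pos[w]) { npos[a] <- npos[a] + 1; npos[b + 1L] <- npos[b + 1L] - 1 }
    else { nneg[a] <- nneg[a] + 1; nneg[b + 1L] <- nneg[b + 1L] - 1 }
  }
  cpos <- cumsum(npos)[seq_len(n_frames)]
  cneg <- cumsum(nneg)[seq_len(n_frames)]
  frame_pt <- cpos >= cneg          # ties positive
  covered <- (cpos + cneg) > 0
  if (any(!covered) && any(covered)) {
    last <- max(which(covered))
    frame_pt[!covered & seq_len(n_frames) > last] <- frame_pt[last]
    # leading uncovered frames (cannot occur with windows starting at row 1)
    frame_pt[!covered & seq_len(n_frames) < min(which(covered))] <-
      frame_pt[min(which(covered))]
  }
  list(frame_playtime = frame_pt, window_positive = pos,
       retained_hours = sum(frame_pt) * hop_seconds / 3600)
}

#' Select analysable playtime frames for one recording
#'
#' Applies the full frame-selection chain: signal quality, not carried, and
#' playtime.  Playtime can come from the ground-truth flag (synthetic
#' streams), a trained classifier, or an explicit logical vector.  The mask
#' intersection is order-independent.  Recordings retaining less than
#' `min_playtime_hours` are flagged `excluded` and should be dropped from
#' feature computation.
#'
#' @param rec a [RecordingSession-class].
#' @param playtime `"truth"`, a `PlaytimeModel`, or a logical per-frame vector.
#' @param min_playtime_hours minimum retained playtime (default 20 min).
#' @return list: `frames` (analysable frame `data.frame`),
#'   `retained_hours`, `excluded` flag and `reason`.
#' @examples
#' cfg <- synthConfig(n_subjects = 1, recordings_per_subject = c(1, 1),
#'                    session_hours_range = c(2, 2), seed = 3)
#' rec <- generateMotorCohort(cfg)$cohort[[1]]
#' sel <- selectAnalysisFrames(rec, playtime = "truth")
#' sel$retained_hours
#' @export
selectAnalysisFrames <- function(rec, playtime = "truth",
                                 min_playtime_hours = 1 / 3) {
  stopifnot(is(rec, "RecordingSession"))
  fr <- rec@frames
  if (identical(playtime, "truth")) {
    if (!"playtime_truth" %in% names(fr))
      stop("recording has no playtime_truth column; supply a classifier")
    pt <- fr$playtime_truth
  } else if (inherits(playtime, "PlaytimeModel")) {
    # windows are built on quality-passing frames only: low-quality
    # segments are discarded upstream of all classifiers
    q <- which(fr$quality_flag)
    pt <- rep(FALSE, nrow(fr))
    if (length(q) > 0L) {
      segs <- superSegments(fr[q, , drop = FALSE])
      pt[q] <- detectPlaytime(segs, playtime, length(q),
                              rec@hopSeconds)$frame_playtime
    }
  } else if (is.logical(playtime) && length(playtime) == nrow(fr)) {
    pt <- playtime
  } else stop("playtime must be \"truth\", a PlaytimeModel, or a logical vector")
  keep <- fr$quality_flag & !fr$carried_flag & pt
  frames <- fr[keep, , drop = FALSE]
  retained <- nrow(frames) * rec@hopSeconds / 3600
  excluded <- retained < min_playtime_hours
  list(frames = frames, retained_hours = retained, excluded = excluded,
       reason = if (excluded)
         sprintf("retained %.2f h < %.2f h minimum", retained, min_playtime_hours)
       else NA_character_)
}
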