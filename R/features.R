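# Recording-level motor features: posture occupancy and posture-conditioned
# movement distributions, the DAP feature vector.

#' Compute motor feature distributions from analysable frames
#'
#' `postureFractions[p]` is the share of frames in posture `p`;
#' `conditionalMovement[p, m]` the share of movement `m` among frames in
#' posture `p` (zero row when the posture never occurs).  Features depend
#' only on category counts, so they are invariant to frame order.
#'
#' @param frames analysable frame `data.frame` (see
#'   [selectAnalysisFrames()]); must be non-empty.
#' @param recording_id identifier stored on the result.
#' @param hop_seconds frame hop, for `analysedHours`.
#' @param postures,movements category inventories; packaged defaults when
#'   `NULL`.
#' @return a [MotorFeatures-class] object.
#' @export
computeFeatures <- function(frames, recording_id = "rec",
                            hop_seconds = 1.15,
                            postures = NULL, movements = NULL) {
  if (!is.data.frame(frames) || nrow(frames) == 0L)
    stop("cannot compute features from an empty frame set ",
         "(recording should have been excluded upstream)")
  cats <- .default_categories()
  if (is.null(postures)) postures <- cats$postures
  if (is.null(movements)) movements <- cats$movements
  pf <- table(factor(frames$posture, levels = postures))
  tab <- table(factor(frames$posture, levels = postures),
               factor(frames$movement, levels = movements))
  cm <- unclass(tab)
  rs <- rowSums(cm)
  cm <- cm / ifelse(rs > 0, rs, 1)
  dimnames(cm) <- list(postures, movements)
  new("MotorFeatures", recordingId = recording_id,
      postureFractions = setNames(as.numeric(pf) / sum(pf), postures),
      conditionalMovement = cm,
      analysedHours = nrow(frames) * hop_seconds / 3600)
}

#' Flatten motor features into the regression feature vector
#'
#' Deterministic concatenation: posture fractions first, then the
#' conditional movement matrix in row-major order.  Cell ordering follows
#' the category inventories and is stable across runs, so the flattening is
#' injective on valid features (see [unflattenFeatures()]).
#'
#' @param f a [MotorFeatures-class].
#' @return named numeric vector of length
#'   `n_postures + n_postures * n_movements`.
#' @export
flattenFeatures <- function(f) {
  stopifnot(is(f, "MotorFeatures"))
  cm <- f@conditionalMovement
  cond <- as.numeric(t(cm))
  names(cond) <- paste0("cond.", rep(rownames(cm), each = ncol(cm)), ".",
                        rep(colnames(cm), nrow(cm)))
  c(setNames(f@postureFractions,
             paste0("posture.", names(f@postureFractions))), cond)
}

#' Reconstruct motor features from a flattened vector
#'
#' Inverse of [flattenFeatures()]; used for round-trip checks.
#'
#' @param v flattened feature vector with the standard cell names.
#' @param recording_id,analysed_hours metadata for the rebuilt object.
#' @return a [MotorFeatures-class].
#' @export
unflattenFeatures <- function(v, recording_id = "rec", analysed_hours = NA_real_) {
  pn <- grep("^posture\\.", names(v), value = TRUE)
  postures <- sub("^posture\\.", "", pn)
  cn <- grep("^cond\\.", names(v), value = TRUE)
  parts <- strsplit(sub("^cond\\.", "", cn), ".", fixed = TRUE)
  movements <- unique(vapply(parts, `[`, character(1), 2L))
  cm <- matrix(v[cn], nrow = length(postures), ncol = length(movements),
               byrow = TRUE, dimnames = list(postures, movements))
  new("MotorFeatures", recordingId = recording_id,
      postureFractions = setNames(as.numeric(v[pn]), postures),
      conditionalMovement = cm,
      analysedHours = as.numeric(analysed_hours))
}

setMethod("show", "MotorFeatures", function(object) {
  cat("MotorFeatures", object@recordingId,
      sprintf("(%.2f analysed h)\n", object@analysedHours))
  pf <- sort(object@postureFractions, decreasing = TRUE)
  cat("  top postures:",
      paste(sprintf("%s %.2f", names(pf)[pf > 0.01], pf[pf > 0.01]),
            collapse = ", "), "\n")
})

#' Build the cohort feature container
#'
#' Runs frame selection and feature computation for every recording of a
#' cohort and assembles the flattened feature vectors into a
#' [MotorFeatureSet-class] (features x recordings), with the manifest and
#' analysed hours in `colData`.  Recordings excluded by the minimum-
#' playtime rule are dropped and listed in
#' `metadata(x)$excluded_recordings`.
#'
#' @param cohort a [RecordingSet-class].
#' @param playtime passed to [selectAnalysisFrames()].
#' @param min_playtime_hours minimum retained playtime per recording.
#' @return a [MotorFeatureSet-class].
#' @examples
#' cfg <- synthConfig(n_subjects = 2, recordings_per_subject = c(1, 2),
#'                    session_hours_range = c(2, 3), seed = 5)
#' mfs <- motorFeatureSet(generateMotorCohort(cfg)$cohort)
#' dim(mfs)
#' @export
motorFeatureSet <- function(cohort, playtime = "truth",
                            min_playtime_hours = 1 / 3) {
  stopifnot(is(cohort, "RecordingSet"))
  man <- manifest(cohort)
  vecs <- list(); hours <- numeric(0); excluded <- character(0)
  for (rid in names(cohort)) {
    rec <- cohort[[rid]]
    sel <- selectAnalysisFrames(rec, playtime, min_playtime_hours)
    if (sel$excluded || nrow(sel$frames) == 0L) {
      excluded <- c(excluded, rid)
      next
    }
    f <- computeFeatures(sel$frames, rid, rec@hopSeconds)
    vecs[[rid]] <- flattenFeatures(f)
    hours[rid] <- f@analysedHours
  }
  if (!length(vecs)) stop("no recording retained enough playtime")
  mat <- do.call(cbind, vecs)
  keep <- match(colnames(mat), man$recording_id)
  cd <- S4Vectors::DataFrame(man[keep, , drop = FALSE])
  cd$analysed_hours <- as.numeric(hours[colnames(mat)])
  rownames(cd) <- colnames(mat)
  cell <- strsplit(rownames(mat), ".", fixed = TRUE)
  rd <- S4Vectors::DataFrame(
    type = ifelse(vapply(cell, `[`, character(1), 1L) == "posture",
                  "posture", "conditional"),
    posture = vapply(cell, `[`, character(1), 2L),
    movement = vapply(cell, function(z) if (length(z) > 2) z[3] else NA_character_,
                      character(1)),
    row.names = rownames(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fraction = mat), rowData = rd, colData = cd,
    metadata = list(excluded_recordings = excluded,
                    min_playtime_hours = min_playtime_hours))
  new("MotorFeatureSet", se)
}

setMethod("manifest", "MotorFeatureSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
setMethod("ages", "MotorFeatureSet", function(x) x$age_months)
setMethod("subjectIds", "MotorFeatureSet", function(x) x$subject_id)
setMethod("datasetTags", "MotorFeatureSet", function(x) x$dataset_tag)

#' Overall per-category fractions of each recording
#'
#' Returns, per recording, the overall time fraction of each posture and of
#' each posture-movement combination (conditional rows multiplied by their
#' posture fraction), i.e. all categories expressed on the common
#' total-time scale.  Summing the combination rows over movements
#' reproduces the posture rows.
#'
#' @param x a [MotorFeatureSet-class].
#' @return matrix categories x recordings; rows named `"<posture>"` and
#'   `"<posture>-<movement>"`.
#' @export
overallFractions <- function(x) {
  stopifnot(is(x, "MotorFeatureSet"))
  mat <- SummarizedExperiment::assay(x, "fraction")
  rd <- SummarizedExperiment::rowData(x)
  post <- mat[rd$type == "posture", , drop = FALSE]
  rownames(post) <- rd$posture[rd$type == "posture"]
  cond <- mat[rd$type == "conditional", , drop = FALSE]
  cp <- rd$posture[rd$type == "conditional"]
  over <- cond * post[cp, , drop = FALSE]
  rownames(over) <- paste0(cp, "-", rd$movement[rd$type == "conditional"])
  rbind(post, over)
}

#' Monthly age-group mean category curves
#'
#' For each category and monthly age bin `[m, m + 1)`, the unweighted mean
#' over recordings of that category's overall fraction.  Empty bins are
#' flagged.
#'
#' @param x a [MotorFeatureSet-class].
#' @param months integer bin starts (default 4 to 18).
#' @return list: `curves` (categories x bins mean-fraction matrix, `NA` in
#'   empty bins), `counts` (recordings per bin), `months`.
#' @export
agegroupMeanCurves <- function(x, months = 4:18) {
  over <- overallFractions(x)
  age <- ages(x)
  bin <- findInterval(age, c(months, max(months) + 1))
  curves <- matrix(NA_real_, nrow(over), length(months),
                   dimnames = list(rownames(over), as.character(months)))
  counts <- integer(length(months))
  for (b in seq_along(months)) {
    sel <- bin == b
    counts[b] <- sum(sel)
    if (counts[b] > 0)
      curves[, b] <- rowMeans(over[, sel, drop = FALSE])
  }
  list(curves = curves, counts = counts, months = months)
}
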