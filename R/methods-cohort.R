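#' @describeIn RecordingSet number of recordings
#' @param x a `RecordingSet`.
#' @export
setMethod("length", "RecordingSet", function(x) length(x@recordings))

#' @describeIn RecordingSet extract one recording by index or id
#' @param i index or recording id.
#' @export
setMethod("[[", "RecordingSet", function(x, i) x@recordings[[i]])

#' @describeIn RecordingSet recording ids
#' @export
setMethod("names", "RecordingSet", function(x) names(x@recordings))

setMethod("manifest", "RecordingSet", function(x) {
  fph <- vapply(x@recordings, function(r) r@hopSeconds, numeric(1))
  data.frame(
    recording_id = vapply(x@recordings, function(r) r@recordingId, character(1)),
    subject_id = vapply(x@recordings, function(r) r@subjectId, character(1)),
    dataset_tag = vapply(x@recordings, function(r) r@datasetTag, character(1)),
    age_months = vapply(x@recordings, function(r) r@ageMonths, numeric(1)),
    total_hours = vapply(x@recordings, function(r)
      nrow(r@frames) * r@hopSeconds / 3600, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("ages", "RecordingSet", function(x)
  vapply(x@recordings, function(r) r@ageMonths, numeric(1), USE.NAMES = FALSE))

setMethod("subjectIds", "RecordingSet", function(x)
  vapply(x@recordings, function(r) r@subjectId, character(1), USE.NAMES = FALSE))

setMethod("datasetTags", "RecordingSet", function(x)
  vapply(x@recordings, function(r) r@datasetTag, character(1), USE.NAMES = FALSE))

setMethod("show", "RecordingSession", function(object) {
  cat("RecordingSession", object@recordingId,
      sprintf("(subject %s, %s)\n", object@subjectId, object@datasetTag))
  cat(sprintf("  age: %.2f months | %d frames (%.2f h at %.2f s hop)\n",
              object@ageMonths, nrow(object@frames),
              nrow(object@frames) * object@hopSeconds / 3600, object@hopSeconds))
  fr <- object@frames
  cat(sprintf("  usable: %.1f%% | carried: %.1f%%",
              100 * mean(fr$quality_flag), 100 * mean(fr$carried_flag)))
  if ("playtime_truth" %in% names(fr))
    cat(sprintf(" | playtime (truth): %.1f%%", 100 * mean(fr$playtime_truth)))
  cat("\n")
})

setMethod("show", "RecordingSet", function(object) {
  m <- manifest(object)
  cat(sprintf("RecordingSet: %d recordings, %d subjects, %.1f h total\n",
              nrow(m), length(unique(m$subject_id)), sum(m$total_hours)))
  cat(sprintf("  ages %.1f-%.1f months | tags: %s\n",
              min(m$age_months), max(m$age_months),
              paste(unique(m$dataset_tag), collapse = ", ")))
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nSubjects, "subjects, ages",
      sprintf("%.1f-%.1f months\n", object@ageRange[1], object@ageRange[2]))
  cat(sprintf("  recordings/subject %d-%d | sessions %.1f-%.1f h\n",
              object@recordingsPerSubject[1], object@recordingsPerSubject[2],
              object@sessionHoursRange[1], object@sessionHoursRange[2]))
  cat(sprintf("  fractions: play %.2f, carried %.2f, low-quality %.2f\n",
              object@playtimeFraction, object@carriedFraction,
              object@lowqualityFraction))
  cat(sprintf("  sigma_dev %.2f mo, sigma_sess %.2f mo, p_stay %.2f, seed %d\n",
              object@sigmaDev, object@sigmaSess, object@pStay, object@seed))
})
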