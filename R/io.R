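# Delimited-text interchange: one stream file per recording plus a cohort
# manifest; the same schema is accepted for real classifier exports.

#' Write a cohort to delimited-text stream files
#'
#' Writes one tab-separated stream file per recording (columns
#' `frame_index`, `posture`, `movement`, `carried_flag`, `quality_flag`
#' and, when present, `playtime_truth`) and a `manifest.tsv` with
#' `recording_id`, `subject_id`, `dataset_tag`, `age_months`,
#' `stream_path`.
#'
#' @param cohort a [RecordingSet-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "RecordingSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- manifest(cohort)
  man$stream_path <- file.path("streams", paste0(man$recording_id, ".tsv"))
  dir.create(file.path(dir, "streams"), showWarnings = FALSE)
  for (i in seq_len(nrow(man))) {
    rec <- cohort[[man$recording_id[i]]]
    write.table(rec@frames, file.path(dir, man$stream_path[i]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man$hop_seconds <- vapply(man$recording_id,
                            function(r) cohort[[r]]@hopSeconds, numeric(1))
  path <- file.path(dir, "manifest.tsv")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a stream manifest
#'
#' @param manifest_path path to a `manifest.tsv` written by
#'   [writeCohort()] (stream paths resolved relative to its directory).
#' @return a [RecordingSet-class].
#' @export
readCohort <- function(manifest_path) {
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    fr <- read.delim(file.path(base, man$stream_path[i]),
                     stringsAsFactors = FALSE)
    new("RecordingSession",
        recordingId = man$recording_id[i], subjectId = man$subject_id[i],
        datasetTag = man$dataset_tag[i], ageMonths = man$age_months[i],
        frames = fr,
        hopSeconds = if ("hop_seconds" %in% names(man))
          man$hop_seconds[i] else 1.15)
  })
  names(recs) <- man$recording_id
  new("RecordingSet", recordings = recs)
}
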