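#' @exportMethod show
NULL

#' Cohort manifest
#'
#' One row per recording: recording id, subject id, dataset tag, age in
#' months, and (where available) total and analysed hours.
#'
#' @param x a [RecordingSet-class] or [MotorFeatureSet-class].
#' @return a `data.frame`.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' Ages at recording, in months
#' @param x a cohort-like object.
#' @return numeric vector of ages.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' Subject identifiers
#' @param x a cohort-like object.
#' @return character vector of subject ids, one per recording.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Dataset tags
#' @param x a cohort-like object.
#' @return character vector of dataset tags, one per recording.
#' @export
setGeneric("datasetTags", function(x) standardGeneric("datasetTags"))

#' Fitted sigmoid parameters
#' @param x a [SigmoidFit-class] or [GrowthChart-class].
#' @return named numeric vector `(L, U, x0, k)`.
#' @export
setGeneric("sigmoidParams", function(x) standardGeneric("sigmoidParams"))

#' Chart goodness-of-fit table
#' @param x a [GrowthChart-class].
#' @return `data.frame` with one row per grouping level.
#' @export
setGeneric("chartQuality", function(x) standardGeneric("chartQuality"))

#' Chart monthly mean/SD table
#' @param x a [GrowthChart-class].
#' @return `data.frame` with one row per monthly bin.
#' @export
setGeneric("chartMonthly", function(x) standardGeneric("chartMonthly"))

#' Per-epoch measurement-noise SD (months)
#' @param x a [NoiseEstimate-class].
#' @return a single number.
#' @export
setGeneric("sigmaNoise", function(x) standardGeneric("sigmaNoise"))
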