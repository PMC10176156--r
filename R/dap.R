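# Developmental age prediction (DAP): Gaussian-process regression of age
# on motor or physical feature vectors, with subject-wise cross-validation.

.feature_matrix <- function(features) {
  if (is(features, "MotorFeatureSet"))
    t(SummarizedExperiment::assay(features, "fraction"))
  else as.matrix(features)
}

#' Fit a developmental age prediction model
#'
#' Gaussian-process regression of chronological age (months) on the
#' flattened feature vector, with an isotropic radial-basis-function kernel
#' plus a white-noise term.  Hyperparameters are chosen by marginal-
#' likelihood maximization over `n_restarts` seeded starts; features and
#' the age target are standardized internally and predictions are
#' re-expressed in months.  Refitting with the same seed gives identical
#' hyperparameters.
#'
#' @param features a [MotorFeatureSet-class] or numeric matrix
#'   (recordings x features).
#' @param ages chronological ages in months; taken from the feature set
#'   when `NULL`.
#' @param seed integer seed for the optimizer restarts.
#' @param n_restarts number of optimizer starts.
#' @param tag model identity label.
#' @return a [DapModel-class].
#' @examples
#' X <- cbind(x = seq(4, 18, length.out = 20))
#' m <- fitDap(X, ages = seq(4, 18, length.out = 20), seed = 1)
#' predictDap(m, X[1:3, , drop = FALSE])
#' @export
fitDap <- function(features, ages = NULL, seed = 1L, n_restarts = 5L,
                   tag = "dap") {
  X <- .feature_matrix(features)
  if (is.null(ages)) {
    stopifnot(is(features, "MotorFeatureSet"))
    ages <- ages(features)
  }
  stopifnot(nrow(X) == length(ages))
  if (nrow(X) < 10L)
    stop("need at least 10 training recordings, got ", nrow(X))
  sds <- apply(X, 2, sd)
  if (all(sds == 0))
    stop("all feature dimensions are constant: ",
         paste(head(colnames(X), 5), collapse = ", "), " ...")
  ctr <- colMeans(X)
  scl <- ifelse(sds > 0, sds, 1)       # constant cells carry no distance
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- mean(ages); ys <- sd(ages)
  if (ys == 0) ys <- 1
  fit <- .gp_fit(Xs, (ages - yc) / ys, seed = seed, n_restarts = n_restarts)
  man <- if (is(features, "MotorFeatureSet"))
    data.frame(recording_id = colnames(features),
               subject_id = subjectIds(features), stringsAsFactors = FALSE)
  else data.frame(recording_id = if (is.null(rownames(X)))
    sprintf("rec%04d", seq_len(nrow(X))) else rownames(X),
    subject_id = NA_character_, stringsAsFactors = FALSE)
  new("DapModel", X = Xs, hyp = fit$theta, alpha = fit$alpha, L = fit$L,
      featCenter = ctr, featScale = scl, yCenter = yc, yScale = ys,
      trainingManifest = man, seed = as.integer(seed),
      tag = sprintf("%s:seed%d", tag, seed))
}

#' Predict developmental age
#'
#' Posterior predictive mean and SD of age, in months, for new feature
#' vectors under a fitted [DapModel-class].
#'
#' @param model a [DapModel-class].
#' @param features a [MotorFeatureSet-class] or matrix with the training
#'   feature dimensions.
#' @return `data.frame` (`DAPResult`): `recording_id`, `dap_months`,
#'   `predictive_sd_months`, `model_tag`.
#' @export
predictDap <- function(model, features) {
  stopifnot(is(model, "DapModel"))
  X <- .feature_matrix(features)
  if (ncol(X) != length(model@featCenter))
    stop("feature dimension mismatch: model expects ",
         length(model@featCenter), ", got ", ncol(X))
  Xs <- sweep(sweep(X, 2, model@featCenter), 2, model@featScale, "/")
  pr <- .gp_predict(list(theta = model@hyp, L = model@L, alpha = model@alpha),
                    model@X, Xs)
  ids <- if (is(features, "MotorFeatureSet")) colnames(features)
  else if (!is.null(rownames(X))) rownames(X)
  else sprintf("q%04d", seq_len(nrow(X)))
  data.frame(recording_id = ids,
             dap_months = pr$mean * model@yScale + model@yCenter,
             predictive_sd_months = pr$sd * model@yScale,
             model_tag = model@tag, row.names = NULL,
             stringsAsFactors = FALSE)
}

setMethod("show", "DapModel", function(object) {
  cat("DapModel", object@tag, "\n")
  cat(sprintf("  %d training recordings, %d feature dims\n",
              nrow(object@X), ncol(object@X)))
  cat(sprintf("  kernel: sf2 %.3g, ell2 %.3g, noise sd %.2f months\n",
              exp(object@hyp[["log_sf2"]]), exp(object@hyp[["log_ell2"]]),
              sqrt(exp(object@hyp[["log_sn2"]])) * object@yScale))
})

.grouped_cv <- function(X, y, groups, ids, seed = 1L, n_restarts = 5L,
                        k = NULL, tag = "cv") {
  ug <- unique(groups)
  if (length(ug) < 2L) stop("need at least 2 subjects for subject-wise CV")
  if (is.null(k) || k >= length(ug)) {
    fold_of <- match(groups, ug)          # LOSO: one fold per subject
    nfold <- length(ug)
  } else {
    perm <- .with_seed(seed, sample(length(ug)))
    fold_of <- (match(match(groups, ug), perm) - 1L) %% k + 1L
    nfold <- k
  }
  out <- vector("list", nfold)
  for (f in seq_len(nfold)) {
    te <- fold_of == f
    if (!any(te)) next
    stopifnot(length(intersect(groups[te], groups[!te])) == 0L)
    m <- fitDap(X[!te, , drop = FALSE], y[!te], seed = seed,
                n_restarts = n_restarts, tag = sprintf("%s-fold%d", tag, f))
    pr <- predictDap(m, X[te, , drop = FALSE])
    pr$recording_id <- ids[te]
    pr$subject_id <- groups[te]
    pr$age_months <- y[te]
    out[[f]] <- pr
  }
  res <- do.call(rbind, out)
  res[match(ids, res$recording_id), , drop = FALSE]
}

#' Leave-one-subject-out cross-validated DAP
#'
#' Predicts each recording's DAP from a model trained on all recordings of
#' all other subjects, so no subject ever appears in both the training and
#' test side of a fold.
#'
#' @param features a [MotorFeatureSet-class], or a matrix with `ages` and
#'   `subjects` supplied.
#' @param ages,subjects per-recording ages and subject ids (taken from the
#'   feature set when `NULL`).
#' @param seed,n_restarts passed to [fitDap()].
#' @param k optional number of subject-grouped folds; `NULL` (default) is
#'   full leave-one-subject-out.
#' @return `data.frame` of DAP results, one row per recording, with
#'   `age_months` and `subject_id` attached.
#' @export
losoCv <- function(features, ages = NULL, subjects = NULL, seed = 1L,
                   n_restarts = 5L, k = NULL) {
  X <- .feature_matrix(features)
  if (is(features, "MotorFeatureSet")) {
    if (is.null(ages)) ages <- ages(features)
    if (is.null(subjects)) subjects <- subjectIds(features)
    ids <- colnames(features)
  } else ids <- if (!is.null(rownames(X))) rownames(X)
  else sprintf("rec%04d", seq_len(nrow(X)))
  stopifnot(!is.null(ages), !is.null(subjects))
  .grouped_cv(X, ages, subjects, ids, seed = seed, n_restarts = n_restarts,
              k = k, tag = "loso")
}

#' Cross-dataset DAP evaluation
#'
#' Fits DAP on one cohort and applies it to another (both directions).
#' The cohorts must carry disjoint dataset tags and recording ids.
#'
#' @param train_features,test_features [MotorFeatureSet-class] objects.
#' @param seed,n_restarts passed to [fitDap()].
#' @return list with `forward` (trained on the first, applied to the
#'   second) and `reverse` DAP result tables.
#' @export
crossDatasetEval <- function(train_features, test_features, seed = 1L,
                             n_restarts = 5L) {
  stopifnot(is(train_features, "MotorFeatureSet"),
            is(test_features, "MotorFeatureSet"))
  ta <- unique(datasetTags(train_features))
  tb <- unique(datasetTags(test_features))
  if (length(intersect(ta, tb)) > 0)
    stop("cohorts must carry disjoint dataset tags")
  if (length(intersect(colnames(train_features), colnames(test_features))) > 0)
    stop("cohorts share recording ids")
  one <- function(tr, te, label) {
    m <- fitDap(tr, seed = seed, n_restarts = n_restarts, tag = label)
    pr <- predictDap(m, te)
    pr$subject_id <- subjectIds(te)
    pr$age_months <- ages(te)
    pr
  }
  list(forward = one(train_features, test_features,
                     paste0("train-", paste(ta, collapse = "+"))),
       reverse = one(test_features, train_features,
                     paste0("train-", paste(tb, collapse = "+"))))
}

#' DAP from physical growth measures
#'
#' Applies the same Gaussian-process machinery to physical growth features:
#' length, weight, head circumference, or all three combined
#' (`"physical3"`), with subject-wise cross-validation as in [losoCv()].
#'
#' @param measurements `data.frame` with `subject_id`, `age_months`,
#'   `length_cm`, `weight_kg`, `hc_cm`.
#' @param modality `"length"`, `"weight"`, `"hc"` or `"physical3"`.
#' @param seed,n_restarts passed to [fitDap()].
#' @param k optional number of subject-grouped folds (`NULL` = LOSO).
#' @return `data.frame` of DAP results, one row per measurement.
#' @export
physicalDap <- function(measurements, modality = c("physical3", "length",
                                                   "weight", "hc"),
                        seed = 1L, n_restarts = 5L, k = NULL) {
  modality <- match.arg(modality)
  cols <- switch(modality,
                 length = "length_cm", weight = "weight_kg", hc = "hc_cm",
                 physical3 = c("length_cm", "weight_kg", "hc_cm"))
  stopifnot(all(c("subject_id", "age_months", cols) %in% names(measurements)))
  X <- as.matrix(measurements[, cols, drop = FALSE])
  rownames(X) <- paste0(measurements$subject_id, ".",
                        ave(seq_len(nrow(X)), measurements$subject_id,
                            FUN = seq_along))
  .grouped_cv(X, measurements$age_months, measurements$subject_id,
              rownames(X), seed = seed, n_restarts = n_restarts, k = k,
              tag = paste0("phys-", modality))
}
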