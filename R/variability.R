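# Measurement-noise estimation from intra-session epoch splits, and
# longitudinal DAP tracking over measurement intervals.

#' Split a recording's playtime into independent 1-hour epochs
#'
#' Recordings retaining strictly more than `min_playtime_hours` of
#' analysable playtime are split into consecutive non-overlapping epochs of
#' `epoch_hours` of playtime (3130 frames per hour at the standard hop);
#' the trailing partial epoch is discarded.  Recordings at or below the
#' threshold yield an empty list.
#'
#' @param rec a [RecordingSession-class].
#' @param playtime passed to [selectAnalysisFrames()].
#' @param min_playtime_hours strict threshold (default 2 h).
#' @param epoch_hours epoch length in playtime hours.
#' @return list of analysable frame `data.frame`s, one per epoch.
#' @export
splitEpochs <- function(rec, playtime = "truth", min_playtime_hours = 2,
                        epoch_hours = 1) {
  sel <- selectAnalysisFrames(rec, playtime, min_playtime_hours = 0)
  if (sel$retained_hours <= min_playtime_hours) return(list())
  epoch_frames <- as.integer(floor(epoch_hours * framesPerHour(rec@hopSeconds)))
  n_ep <- floor(nrow(sel$frames) / epoch_frames)
  lapply(seq_len(n_ep), function(e)
    sel$frames[((e - 1L) * epoch_frames + 1L):(e * epoch_frames), ,
               drop = FALSE])
}

#' DAP of each epoch of each eligible recording
#'
#' Convenience wrapper: splits every recording of a cohort into playtime
#' epochs, computes epoch-level motor features and predicts their DAP with
#' a fitted model.
#'
#' @param cohort a [RecordingSet-class].
#' @param model a [DapModel-class].
#' @param playtime,min_playtime_hours,epoch_hours passed to [splitEpochs()].
#' @return `data.frame`: `recording_id`, `epoch`, `dap_months`,
#'   `age_months`.
#' @export
epochDaps <- function(cohort, model, playtime = "truth",
                      min_playtime_hours = 2, epoch_hours = 1) {
  out <- list()
  for (rid in names(cohort)) {
    rec <- cohort[[rid]]
    eps <- splitEpochs(rec, playtime, min_playtime_hours, epoch_hours)
    if (length(eps) < 1L) next
    feats <- t(vapply(eps, function(fr)
      flattenFeatures(computeFeatures(fr, rid, rec@hopSeconds)),
      numeric(length(model@featCenter))))
    pr <- predictDap(model, feats)
    out[[rid]] <- data.frame(recording_id = rid,
                             epoch = seq_along(eps),
                             dap_months = pr$dap_months,
                             age_months = rec@ageMonths,
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(recording_id = character(0), epoch = integer(0),
                      dap_months = numeric(0), age_months = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Intra-session DAP measurement noise
#'
#' All unordered pairs of epoch DAPs within each recording contribute a
#' difference; the per-epoch noise SD is `SD(differences) / sqrt(2)`, since
#' a difference of two independent equal-variance epochs has twice the
#' per-epoch variance.  The standardized differences are tested against
#' the standard normal (one-sample Kolmogorov-Smirnov), and the noise
#' level is correlated with age (Pearson, on absolute differences by
#' default).
#'
#' @param epoch_daps `data.frame` from [epochDaps()] (columns
#'   `recording_id`, `epoch`, `dap_months`, `age_months`).
#' @param signed correlate signed rather than absolute differences with age.
#' @return a [NoiseEstimate-class].
#' @export
intraSessionNoise <- function(epoch_daps, signed = FALSE) {
  stopifnot(all(c("recording_id", "epoch", "dap_months", "age_months")
                %in% names(epoch_daps)))
  pairs <- list()
  for (rid in unique(epoch_daps$recording_id)) {
    d <- epoch_daps[epoch_daps$recording_id == rid, , drop = FALSE]
    if (nrow(d) < 2L) next
    cmb <- utils::combn(nrow(d), 2L)
    pairs[[rid]] <- data.frame(
      recording_id = rid,
      epoch_i = d$epoch[cmb[1, ]], epoch_j = d$epoch[cmb[2, ]],
      dap_diff = d$dap_months[cmb[2, ]] - d$dap_months[cmb[1, ]],
      age_months = d$age_months[1], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs))
    do.call(rbind, c(pairs, list(make.row.names = FALSE))) else NULL
  if (is.null(pairs) || nrow(pairs) < 2L)
    stop("need at least 2 epoch pairs to estimate measurement noise")
  diffs <- pairs$dap_diff
  sigma <- sd(diffs) / sqrt(2)
  ks_p <- NA_real_
  if (sd(diffs) > 0) {
    z <- (diffs - mean(diffs)) / sd(diffs)
    ks_p <- unname(suppressWarnings(ks.test(z, "pnorm"))$p.value)
  }
  xcor <- if (signed) diffs else abs(diffs)
  r <- p <- NA_real_
  if (sd(xcor) > 0 && sd(pairs$age_months) > 0) {
    ct <- suppressWarnings(cor.test(xcor, pairs$age_months))
    r <- unname(ct$estimate); p <- unname(ct$p.value)
  }
  new("NoiseEstimate", pairs = pairs, sigmaNoise = sigma,
      ksP = ks_p, ageCorrR = r, ageCorrP = p, nPairs = nrow(pairs))
}

setMethod("sigmaNoise", "NoiseEstimate", function(x) x@sigmaNoise)

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: %d epoch pairs\n", object@nPairs))
  cat(sprintf("  per-epoch noise SD = %.3f months (diff SD / sqrt(2))\n",
              object@sigmaNoise))
  cat(sprintf("  K-S vs standard normal p = %.3f | |diff|-age Pearson r = %.2f (p = %.3f)\n",
              object@ksP, object@ageCorrR, object@ageCorrP))
})

#' Longitudinal DAP change pairs
#'
#' For every subject with repeated measurements, all ordered pairs
#' `t1 > t0` give a measurement interval `delta_age` and an observed DAP
#' advance `delta_dap`; `k` recordings yield `k (k - 1) / 2` pairs.
#'
#' @param dap_results `data.frame` with `subject_id`, `age_months`,
#'   `dap_months`.
#' @return `data.frame` (`DeltaPair`): `subject_id`, `age_t0`,
#'   `delta_age` (> 0), `delta_dap`.
#' @export
pairDeltas <- function(dap_results) {
  stopifnot(all(c("subject_id", "age_months", "dap_months")
                %in% names(dap_results)))
  out <- list()
  for (s in unique(dap_results$subject_id)) {
    d <- dap_results[dap_results$subject_id == s, , drop = FALSE]
    d <- d[order(d$age_months), , drop = FALSE]
    if (nrow(d) < 2L) next
    cmb <- utils::combn(nrow(d), 2L)
    da <- d$age_months[cmb[2, ]] - d$age_months[cmb[1, ]]
    keep <- da > 0
    out[[s]] <- data.frame(
      subject_id = s, age_t0 = d$age_months[cmb[1, keep]],
      delta_age = da[keep],
      delta_dap = d$dap_months[cmb[2, keep]] - d$dap_months[cmb[1, keep]],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(subject_id = character(0), age_t0 = numeric(0),
                      delta_age = numeric(0), delta_dap = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Binned statistics of DAP advance versus measurement interval
#'
#' Means and SDs of `delta_dap` in monthly `delta_age` bins `[m, m + 1)`.
#' Bins with fewer than `min_count` pairs are flagged and excluded from
#' the monotonicity summary.
#'
#' @param pairs output of [pairDeltas()].
#' @param months bin starts in months.
#' @param min_count minimum pairs per reliable bin.
#' @return list: `table` (`data.frame` per bin: `delta_age_bin`, `mean`,
#'   `sd`, `n`, `flagged`), `monotone` (are the unflagged bin means
#'   non-decreasing in the interval).
#' @export
deltaBinStats <- function(pairs, months = 1:10, min_count = 3L) {
  stopifnot(nrow(pairs) >= 1L)
  bin <- findInterval(pairs$delta_age, c(months, max(months) + 1))
  tab <- data.frame(delta_age_bin = months,
                    mean = NA_real_, sd = NA_real_, n = 0L, flagged = TRUE)
  for (b in seq_along(months)) {
    sel <- bin == b
    tab$n[b] <- sum(sel)
    if (tab$n[b] > 0) {
      tab$mean[b] <- mean(pairs$delta_dap[sel])
      tab$sd[b] <- if (tab$n[b] > 1) sd(pairs$delta_dap[sel]) else NA_real_
    }
    tab$flagged[b] <- tab$n[b] < min_count
  }
  good <- tab$mean[!tab$flagged]
  list(table = tab,
       monotone = length(good) < 2L || all(diff(good) >= 0))
}
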