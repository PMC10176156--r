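# Growth-chart machinery: four-parameter logistic mean models of DAP
# versus age, goodness-of-fit at three grouping levels, mixed-model
# serial-measurement correction, and bootstrap confidence intervals.

.sigmoid <- function(x, L, U, x0, k) L + (U - L) / (1 + exp(-k * (x - x0)))

#' Fit a four-parameter logistic sigmoid
#'
#' Least-squares fit of `f(x) = L + (U - L) / (1 + exp(-k (x - x0)))` with
#' data-driven multi-start initialization (`L = min`, `U = max`,
#' `x0 = median(x)`, slope starts `k` in 0.2/0.5/1, mirrored when the
#' response decreases); the start with the lowest residual sum of squares
#' wins.  A (near-)constant response returns a flat degenerate fit rather
#' than an error.
#'
#' @param ages predictor (months); must not be all equal.
#' @param values response (DAP months or measurement values).
#' @param k_starts slope initializations (1/months).
#' @return a [SigmoidFit-class].
#' @examples
#' x <- seq(4, 18, length.out = 30)
#' fitSigmoid(x, 4 + 14 / (1 + exp(-0.8 * (x - 11))))
#' @export
fitSigmoid <- function(ages, values, k_starts = c(0.2, 0.5, 1)) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(ages) < 5L) stop("need at least 5 points to fit a sigmoid")
  if (sd(ages) == 0) stop("ages must not be all equal")
  if (sd(values) < 1e-12) {
    return(new("SigmoidFit",
               params = c(L = mean(values), U = mean(values),
                          x0 = median(ages), k = 0),
               sse = sum((values - mean(values))^2), converged = TRUE,
               degenerate = TRUE, n = length(ages)))
  }
  if (cor(ages, values) < 0) k_starts <- -k_starts
  df <- data.frame(x = ages, y = values)
  span <- diff(range(values))
  best <- NULL; diag_msgs <- character(0)
  for (k0 in k_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ L + (U - L) / (1 + exp(-k * (x - x0))), data = df,
        start = list(L = min(values), U = max(values),
                     x0 = median(ages), k = k0),
        lower = c(min(values) - 2 * span, min(values) - 2 * span,
                  min(ages) - 24, -10),
        upper = c(max(values) + 2 * span, max(values) + 2 * span,
                  max(ages) + 24, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diag_msgs <<- c(diag_msgs, conditionMessage(e)); NULL
      })
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = coef(fit), sse = sse)
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from every start: ",
         paste(unique(diag_msgs), collapse = "; "))
  p <- best$par
  if (p[["U"]] < p[["L"]]) {          # canonical orientation: U >= L, k flips
    p <- c(L = p[["U"]], U = p[["L"]], x0 = p[["x0"]], k = -p[["k"]])
  }
  new("SigmoidFit", params = c(L = p[["L"]], U = p[["U"]],
                               x0 = p[["x0"]], k = p[["k"]]),
      sse = best$sse, converged = TRUE, degenerate = FALSE,
      n = length(ages))
}

setMethod("sigmoidParams", "SigmoidFit", function(x) x@params)

#' @describeIn fitSigmoid evaluate a fitted sigmoid at new ages
#' @param object a [SigmoidFit-class].
#' @param newdata numeric ages.
#' @export
setMethod("predict", "SigmoidFit", function(object, newdata) {
  p <- object@params
  .sigmoid(newdata, p[["L"]], p[["U"]], p[["x0"]], p[["k"]])
})

setMethod("show", "SigmoidFit", function(object) {
  p <- object@params
  cat(sprintf("SigmoidFit: L=%.2f U=%.2f x0=%.2f k=%.3f (n=%d%s)\n",
              p[["L"]], p[["U"]], p[["x0"]], p[["k"]], object@n,
              if (object@degenerate) ", degenerate" else ""))
})

#' Serial-measurement (random-intercept) correction of chart residuals
#'
#' Two-stage correction: residuals from the fitted mean curve,
#' `r_ij = value_ij - f(age_ij)`, are decomposed by a random-intercept
#' model `r_ij = b_i + e_ij` fitted by REML; the corrected residuals are
#' the within-subject parts `e_ij`.  When no subject has repeated
#' measurements the raw residuals are returned with a warning.
#'
#' @param ages,values chart points.
#' @param subject_ids subject identifier per point.
#' @param fit the [SigmoidFit-class] mean model.
#' @return list: `intercepts` (named per-subject), `corrected` residuals,
#'   `sigma_idcontrolled` (the REML within-subject residual SD; the RMS of
#'   the empirical corrected residuals is biased low because the fitted
#'   intercept absorbs part of the within-subject noise),
#'   `intercept_sd`, `residual_sd` (REML variance components),
#'   `raw_residuals`.
#' @export
lmeCorrection <- function(ages, values, subject_ids, fit) {
  r <- values - predict(fit, ages)
  reps <- table(subject_ids)
  if (sum(reps >= 2) < 2) {
    warning("fewer than 2 subjects with repeated measurements; ",
            "returning raw residuals")
    return(list(intercepts = setNames(rep(0, length(reps)), names(reps)),
                corrected = r, sigma_idcontrolled = sqrt(mean(r^2)),
                intercept_sd = NA_real_, residual_sd = NA_real_,
                raw_residuals = r))
  }
  df <- data.frame(r = r, id = factor(subject_ids))
  lf <- suppressMessages(lme4::lmer(r ~ 1 + (1 | id), data = df, REML = TRUE))
  e <- resid(lf)
  vc <- as.data.frame(lme4::VarCorr(lf))
  list(intercepts = setNames(lme4::ranef(lf)$id[, 1],
                             rownames(lme4::ranef(lf)$id)),
       corrected = as.numeric(e),
       sigma_idcontrolled = vc$sdcor[vc$grp == "Residual"],
       intercept_sd = vc$sdcor[vc$grp == "id"],
       residual_sd = vc$sdcor[vc$grp == "Residual"],
       raw_residuals = r)
}

.monthly_bins <- function(ages) floor(ages)

#' Goodness-of-fit of a chart model
#'
#' `R^2 = 1 - SS_res / SS_tot` and `sigma` = root-mean-square residual (in
#' months), at one of three grouping levels: `raw` (every point),
#' `monthly_means` (bin-mean values against the model at bin-mean ages,
#' monthly bins `[m, m + 1)`), or `id_controlled` (residuals after removing
#' per-subject random intercepts, see [lmeCorrection()]).  A zero-variance
#' response reports `R^2 = 0` with a flag.
#'
#' @param fit a [SigmoidFit-class].
#' @param ages,values chart points.
#' @param grouping one of `"raw"`, `"monthly_means"`, `"id_controlled"`.
#' @param subject_ids required for `id_controlled`.
#' @return one-row `data.frame`: `grouping`, `r2`, `sigma`, `n`,
#'   `degenerate`.
#' @export
goodnessOfFit <- function(fit, ages, values,
                          grouping = c("raw", "monthly_means",
                                       "id_controlled"),
                          subject_ids = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "raw") {
    res <- values - predict(fit, ages)
    tot <- values
    n <- length(values)
  } else if (grouping == "monthly_means") {
    bin <- .monthly_bins(ages)
    ma <- tapply(ages, bin, mean)
    mv <- tapply(values, bin, mean)
    res <- as.numeric(mv) - predict(fit, as.numeric(ma))
    tot <- as.numeric(mv)
    n <- length(mv)
  } else {
    if (is.null(subject_ids))
      stop("id_controlled grouping needs subject_ids")
    lc <- lmeCorrection(ages, values, subject_ids, fit)
    n <- length(values)
    ms_tot <- mean((values - mean(values))^2)
    sigma <- lc$sigma_idcontrolled
    degenerate <- ms_tot < 1e-12
    r2 <- if (degenerate) 0 else 1 - sigma^2 / ms_tot
    return(data.frame(grouping = grouping, r2 = r2, sigma = sigma, n = n,
                      degenerate = degenerate, stringsAsFactors = FALSE))
  }
  ss_tot <- sum((tot - mean(tot))^2)
  degenerate <- ss_tot < 1e-12
  r2 <- if (degenerate) 0 else 1 - sum(res^2) / ss_tot
  data.frame(grouping = grouping, r2 = r2, sigma = sqrt(mean(res^2)),
             n = n, degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the rows of `data` with replacement -- at the recording level,
#' or by whole subjects (cluster bootstrap) -- and returns the 2.5/97.5
#' percentile interval of a metric across `n_boot` resamples.  Resamples on
#' which the metric is undefined are redrawn (up to ten times `n_boot`,
#' with a count reported).  The same seed gives the identical interval.
#'
#' @param metric_fn function of a resampled `data.frame` returning a
#'   numeric scalar or named vector.
#' @param data `data.frame` of units.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param unit `"recording"` (rows) or `"subject"` (clusters).
#' @param subject_ids required when `unit = "subject"`.
#' @param seed integer seed.
#' @return list: `ci` (2 x p matrix, rows `lower`/`upper`), `estimate`
#'   (metric on the full data), `n_redrawn`.
#' @examples
#' bootstrapCi(function(d) mean(d$x), data.frame(x = rnorm(50)),
#'             n_boot = 200, seed = 1)$ci
#' @export
bootstrapCi <- function(metric_fn, data, n_boot = 10000,
                        unit = c("recording", "subject"),
                        subject_ids = NULL, seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(n_boot >= 100)
  if (unit == "subject" && is.null(subject_ids))
    stop("subject bootstrap needs subject_ids")
  est <- metric_fn(data)
  draws <- matrix(NA_real_, n_boot, length(est))
  colnames(draws) <- names(est)
  n_redrawn <- 0L
  .with_seed(seed, {
    b <- 1L; tries <- 0L
    while (b <= n_boot && tries < 10L * n_boot) {
      tries <- tries + 1L
      if (unit == "recording") {
        idx <- sample.int(nrow(data), replace = TRUE)
      } else {
        us <- unique(subject_ids)
        pick <- sample(us, replace = TRUE)
        idx <- unlist(lapply(pick, function(s) which(subject_ids == s)),
                      use.names = FALSE)
      }
      val <- tryCatch(metric_fn(data[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(val) || any(!is.finite(val))) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      draws[b, ] <- val
      b <- b + 1L
    }
    if (b <= n_boot) stop("metric undefined on too many bootstrap resamples")
  })
  ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  list(ci = ci, estimate = est, n_redrawn = n_redrawn)
}

#' Build a growth chart for one modality
#'
#' Fits the 4PL mean model of DAP (or a physical measure) versus age and
#' assembles the chart bundle: goodness-of-fit at the raw, monthly-mean and
#' ID-controlled levels with bootstrap 95% CIs, bootstrap CIs of the four
#' sigmoid parameters, a monthly mean/SD table, and the +/- 1 SD band
#' half-width (`sigma_raw`).  Raw and grouped metrics are bootstrapped at
#' the recording level, ID-controlled metrics by whole subjects.
#'
#' @param data `data.frame` with `age_months`, `value` and `subject_id`
#'   (e.g. a DAP result table with `value = dap_months`).
#' @param modality modality tag stored on the chart.
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed integer seed.
#' @param min_n,min_span_bins minimum measurements and occupied monthly
#'   bins required.
#' @return a [GrowthChart-class].
#' @export
buildChart <- function(data, modality = "motor", n_boot = 2000, seed = 1L,
                       min_n = 15L, min_span_bins = 6L) {
  stopifnot(all(c("age_months", "value", "subject_id") %in% names(data)))
  data <- data[is.finite(data$age_months) & is.finite(data$value), ,
               drop = FALSE]
  nb <- length(unique(.monthly_bins(data$age_months)))
  if (nrow(data) < min_n || nb < min_span_bins)
    stop(sprintf("insufficient span: %d measurements over %d monthly bins",
                 nrow(data), nb))
  fit <- fitSigmoid(data$age_months, data$value)
  q_raw <- goodnessOfFit(fit, data$age_months, data$value, "raw")
  q_grp <- goodnessOfFit(fit, data$age_months, data$value, "monthly_means")
  q_id <- goodnessOfFit(fit, data$age_months, data$value, "id_controlled",
                        subject_ids = data$subject_id)

  raw_metric <- function(d) {
    f <- fitSigmoid(d$age_months, d$value)
    c(sigmoidParams(f),
      r2_raw = goodnessOfFit(f, d$age_months, d$value, "raw")$r2,
      sigma_raw = goodnessOfFit(f, d$age_months, d$value, "raw")$sigma,
      r2_grouped = goodnessOfFit(f, d$age_months, d$value,
                                 "monthly_means")$r2,
      sigma_grouped = goodnessOfFit(f, d$age_months, d$value,
                                    "monthly_means")$sigma)
  }
  id_metric <- function(d) {
    f <- fitSigmoid(d$age_months, d$value)
    q <- suppressWarnings(goodnessOfFit(f, d$age_months, d$value,
                                        "id_controlled",
                                        subject_ids = d$subject_id))
    c(r2_id = q$r2, sigma_id = q$sigma)
  }
  bs_raw <- bootstrapCi(raw_metric, data, n_boot = n_boot,
                        unit = "recording", seed = seed)
  bs_id <- bootstrapCi(id_metric, data, n_boot = n_boot, unit = "subject",
                       subject_ids = data$subject_id, seed = seed + 1L)
  ci <- cbind(bs_raw$ci, bs_id$ci)
  quality <- data.frame(
    grouping = c("raw", "monthly_means", "id_controlled"),
    r2 = c(q_raw$r2, q_grp$r2, q_id$r2),
    r2_lo = ci["lower", c("r2_raw", "r2_grouped", "r2_id")],
    r2_hi = ci["upper", c("r2_raw", "r2_grouped", "r2_id")],
    sigma = c(q_raw$sigma, q_grp$sigma, q_id$sigma),
    sigma_lo = ci["lower", c("sigma_raw", "sigma_grouped", "sigma_id")],
    sigma_hi = ci["upper", c("sigma_raw", "sigma_grouped", "sigma_id")],
    n = c(q_raw$n, q_grp$n, q_id$n),
    row.names = NULL, stringsAsFactors = FALSE)
  params_ci <- ci[, c("L", "U", "x0", "k"), drop = FALSE]
  bin <- .monthly_bins(data$age_months)
  monthly <- data.frame(
    month = as.integer(names(table(bin))),
    mean = as.numeric(tapply(data$value, bin, mean)),
    sd = as.numeric(tapply(data$value, bin, sd)),
    n = as.integer(table(bin)), row.names = NULL)
  chart <- new("GrowthChart", modality = modality, fit = fit,
               quality = quality, monthly = monthly,
               data = data.frame(age_months = data$age_months,
                                 value = data$value,
                                 subject_id = data$subject_id,
                                 stringsAsFactors = FALSE),
               bandSd = q_raw$sigma)
  attr(chart@quality, "params_ci") <- params_ci
  chart
}

setMethod("sigmoidParams", "GrowthChart", function(x) x@fit@params)
setMethod("chartQuality", "GrowthChart", function(x) x@quality)
setMethod("chartMonthly", "GrowthChart", function(x) x@monthly)

#' Bootstrap CIs of the four sigmoid parameters of a chart
#' @param x a [GrowthChart-class].
#' @return 2 x 4 matrix (`lower`/`upper` by `L`,`U`,`x0`,`k`).
#' @export
chartParamsCi <- function(x) {
  stopifnot(is(x, "GrowthChart"))
  attr(x@quality, "params_ci")
}

setMethod("show", "GrowthChart", function(object) {
  cat(sprintf("GrowthChart [%s]: %d measurements, %d subjects\n",
              object@modality, nrow(object@data),
              length(unique(object@data$subject_id))))
  p <- object@fit@params
  cat(sprintf("  4PL: L=%.2f U=%.2f x0=%.2f k=%.3f | band +/- %.2f months\n",
              p[["L"]], p[["U"]], p[["x0"]], p[["k"]], object@bandSd))
  q <- object@quality
  for (i in seq_len(nrow(q)))
    cat(sprintf("  %-13s R2 = %.3f [%.3f, %.3f]  sigma = %.2f [%.2f, %.2f] months\n",
                q$grouping[i], q$r2[i], q$r2_lo[i], q$r2_hi[i],
                q$sigma[i], q$sigma_lo[i], q$sigma_hi[i]))
})
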