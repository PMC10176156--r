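# Replicability metrics between two cohorts: per-category age-curve
# agreement and DAP growth-chart agreement.

#' Compare monthly category curves between two cohorts
#'
#' Per category, Pearson's r (with two-sided p) and the mean absolute
#' error in percentage points between the monthly mean curves of two
#' cohorts, using only bins populated in both.  Categories with fewer than
#' 3 shared bins are skipped; zero-variance (degenerate) categories report
#' their MAE but no correlation and are flagged.  Group summaries (mean
#' and range) are reported separately for posture categories and
#' posture-conditioned movement categories.
#'
#' @param curves_a,curves_b outputs of [agegroupMeanCurves()] on the same
#'   bin grid and category inventory.
#' @param drop_degenerate when `FALSE`, computes r for near-degenerate
#'   categories anyway (flagging is the default behaviour).
#' @return list: `table` (`data.frame`: `category`, `type`, `n_bins`, `r`,
#'   `p`, `mae_pp`, `flag`) and `summary` (per category group, mean and
#'   range of r and MAE).
#' @export
compareCategoryCurves <- function(curves_a, curves_b,
                                  drop_degenerate = TRUE) {
  if (!identical(rownames(curves_a$curves), rownames(curves_b$curves)))
    stop("category inventories differ between cohorts")
  if (!identical(curves_a$months, curves_b$months))
    stop("bin grids differ between cohorts")
  cats <- rownames(curves_a$curves)
  rows <- lapply(cats, function(cc) {
    a <- curves_a$curves[cc, ]
    b <- curves_b$curves[cc, ]
    ok <- is.finite(a) & is.finite(b)
    type <- if (grepl("-", cc, fixed = TRUE)) "movement" else "posture"
    if (sum(ok) < 3L)
      return(data.frame(category = cc, type = type, n_bins = sum(ok),
                        r = NA_real_, p = NA_real_, mae_pp = NA_real_,
                        flag = "too_few_bins", stringsAsFactors = FALSE))
    mae <- mean(abs(a[ok] - b[ok])) * 100
    degenerate <- sd(a[ok]) < 1e-12 || sd(b[ok]) < 1e-12
    if (degenerate && drop_degenerate)
      return(data.frame(category = cc, type = type, n_bins = sum(ok),
                        r = NA_real_, p = NA_real_, mae_pp = mae,
                        flag = "degenerate", stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(a[ok], b[ok]))
    data.frame(category = cc, type = type, n_bins = sum(ok),
               r = unname(ct$estimate), p = unname(ct$p.value),
               mae_pp = mae, flag = "", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rng <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  summ <- do.call(rbind, lapply(split(tab, tab$type), function(d) {
    d <- d[d$flag %in% c("", "degenerate"), , drop = FALSE]
    data.frame(type = d$type[1],
               mean_r = rng(d$r, mean), min_r = rng(d$r, min),
               max_r = rng(d$r, max),
               mean_mae_pp = rng(d$mae_pp, mean),
               min_mae_pp = rng(d$mae_pp, min),
               max_mae_pp = rng(d$mae_pp, max),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Compare two DAP growth charts
#'
#' Agreement between the charts of two cohorts built on the same monthly
#' grid: Pearson correlation between the monthly DAP means, per-parameter
#' overlap of the bootstrap 95% CIs of the four sigmoid parameters, and
#' the fraction of the age axis on which the +/- 1 SD bands overlap.
#'
#' @param chart_a,chart_b [GrowthChart-class] objects with bootstrap
#'   parameter CIs (see [buildChart()]).
#' @param age_grid grid on which band overlap is evaluated.
#' @return list: `agegroup_dap_r`, `agegroup_dap_p`, `n_shared_bins`,
#'   `params_overlap` (named logical), `band_overlap_fraction`.
#' @export
compareDapModels <- function(chart_a, chart_b,
                             age_grid = seq(4, 18, by = 0.25)) {
  stopifnot(is(chart_a, "GrowthChart"), is(chart_b, "GrowthChart"))
  ma <- chart_a@monthly; mb <- chart_b@monthly
  shared <- intersect(ma$month, mb$month)
  if (length(shared) < 3L) stop("charts share fewer than 3 monthly bins")
  a <- ma$mean[match(shared, ma$month)]
  b <- mb$mean[match(shared, mb$month)]
  ct <- suppressWarnings(cor.test(a, b))
  ca <- chartParamsCi(chart_a); cb <- chartParamsCi(chart_b)
  overlap <- vapply(colnames(ca), function(p)
    ca["lower", p] <= cb["upper", p] && cb["lower", p] <= ca["upper", p],
    logical(1))
  fa <- predict(chart_a@fit, age_grid); fb <- predict(chart_b@fit, age_grid)
  band <- mean((fa - chart_a@bandSd) <= (fb + chart_b@bandSd) &
                 (fb - chart_b@bandSd) <= (fa + chart_a@bandSd))
  list(agegroup_dap_r = unname(ct$estimate),
       agegroup_dap_p = unname(ct$p.value),
       n_shared_bins = length(shared),
       params_overlap = overlap,
       band_overlap_fraction = band)
}
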