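#' Select the analysis curve of a trial
#'
#' A "curve" is a maximal contiguous stretch of the \eqn{\Delta z} series
#' lying strictly on one side of zero between consecutive zero crossings
#' (samples equal to exactly zero act as boundaries). For the social paradigm
#' the curve containing the event start (t = 0) is selected; for looming, the
#' curve with the largest temporal overlap with the 5--8 s full-expansion
#' period, ties going to the earlier curve.
#'
#' @param rel_time,dz numeric vectors (one trial).
#' @param paradigm `"social"` or `"looming"`.
#' @param overlap_window looming only: the target window (default `c(5, 8)`).
#' @return list with `start_s`, `end_s`, `idx` (sample indices), `sign`
#'   (+1/-1), and `status` (`"ok"` or `"no_curve"`).
#' @export
select_curve <- function(rel_time, dz, paradigm = c("social", "looming"),
                         overlap_window = c(5, 8)) {
  paradigm <- match.arg(paradigm)
  s <- sign(dz)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep))
    return(list(start_s = NA_real_, end_s = NA_real_, idx = integer(),
                sign = 0, status = "no_curve"))
  starts <- starts[keep]; ends <- ends[keep]; vals <- r$values[keep]

  if (paradigm == "social") {
    # curve containing t = 0 (first sample at or after 0 that is nonzero)
    i0 <- which(rel_time >= 0 & s != 0)[1]
    if (is.na(i0))
      return(list(start_s = NA_real_, end_s = NA_real_, idx = integer(),
                  sign = 0, status = "no_curve"))
    pick <- which(starts <= i0 & ends >= i0)
  } else {
    t_lo <- pmax(rel_time[starts], overlap_window[1])
    t_hi <- pmin(rel_time[ends], overlap_window[2])
    ov <- pmax(0, t_hi - t_lo)
    if (max(ov) <= 0)
      return(list(start_s = NA_real_, end_s = NA_real_, idx = integer(),
                  sign = 0, status = "no_curve"))
    pick <- which(ov >= max(ov) - 1e-9)[1]  # tie (to rounding) -> earliest region
  }
  idx <- starts[pick]:ends[pick]
  list(start_s = rel_time[starts[pick]], end_s = rel_time[ends[pick]],
       idx = idx, sign = vals[pick], status = "ok")
}

#' Detect the trial peak within a curve
#'
#' Candidate peaks are local extrema of `dz` inside the curve region, in the
#' curve's own polarity (maxima on positive curves, minima on negative ones;
#' region endpoints count one-sidedly). A candidate is ignored when its
#' height above the trial minimum (positive curves) or depth below the trial
#' maximum (negative curves) is less than `ignore_fraction` of the
#' minimum-to-maximum range of the *whole trial*. Of the surviving
#' candidates the most extreme wins; ties go to the earliest time.
#'
#' @param rel_time,dz one trial.
#' @param curve a region from [select_curve()].
#' @param ignore_fraction 0.05 for social trials, 0.10 for looming.
#' @return list `peak_dz`, `t_peak`, or `NULL` when no candidate survives.
#' @export
detect_peak <- function(rel_time, dz, curve, ignore_fraction = 0.05) {
  if (curve$status != "ok" || length(curve$idx) == 0) return(NULL)
  y <- dz * curve$sign        # work in positive polarity
  idx <- curve$idx
  yr <- y[idx]
  m <- length(yr)
  left  <- c(-Inf, yr[-m])
  right <- c(yr[-1], -Inf)
  cand <- which(yr >= left & yr >= right)
  if (length(cand) == 0) return(NULL)

  rng <- max(dz) - min(dz)
  height <- if (curve$sign > 0) dz[idx[cand]] - min(dz) else max(dz) - dz[idx[cand]]
  cand <- cand[height >= ignore_fraction * rng]
  if (length(cand) == 0) return(NULL)

  best <- cand[which.max(yr[cand])]   # which.max takes the earliest on ties
  list(peak_dz = dz[idx[best]], t_peak = rel_time[idx[best]])
}

#' Signed area under the curve
#'
#' Trapezoidal integral of `dz` over the curve region, in z-score seconds.
#' Negative curves yield negative areas.
#'
#' @param rel_time,dz one trial.
#' @param curve a region from [select_curve()].
#' @return numeric scalar, or `NA` for regions shorter than two samples.
#' @export
compute_auc <- function(rel_time, dz, curve) {
  if (curve$status != "ok" || length(curve$idx) < 2L) return(NA_real_)
  pracma::trapz(rel_time[curve$idx], dz[curve$idx])
}

#' Epoch means of a looming trial
#'
#' Mean \eqn{\Delta z} over the full-expansion epoch (5--8 s, closed), the
#' poststimulus epoch (strictly after 8 s up to 15 s), and the baseline
#' window. "Strictly after 8 s" generalizes the first poststimulus sample to
#' any sampling rate.
#'
#' @param rel_time,dz one trial.
#' @param baseline_window `c(start_s, end_s)`.
#' @return list `baseline`, `loom`, `post`.
#' @export
epoch_means <- function(rel_time, dz, baseline_window = c(-5, 0)) {
  dt <- rel_time[2] - rel_time[1]
  bounds <- list(baseline = baseline_window, loom = c(5, 8), post = c(8, 15))
  win <- list(baseline = rel_time >= baseline_window[1] & rel_time <= baseline_window[2],
              loom = rel_time >= 5 & rel_time <= 8,
              post = rel_time > 8 & rel_time <= 15)
  for (w in names(win)) {
    b <- bounds[[w]]
    covered <- any(win[[w]]) &&
      min(rel_time) <= b[1] + dt / 2 && max(rel_time) >= b[2] - dt / 2
    if (!covered)
      stop_fc(sprintf("trial does not cover the %s epoch", w))
  }
  lapply(win, function(i) mean(dz[i]))
}

#' Per-trial metrics table
#'
#' Computes the curve region, peak \eqn{\Delta z}, time of peak, signed AUC,
#' and (looming) epoch means for every included trial.
#'
#' @param trials an `fp_trials` table (run [apply_qc()] first; only included
#'   trials are measured).
#' @param ignore_fraction peak-ignore threshold; defaults to 0.05 for social
#'   and 0.10 for looming trials.
#' @return tibble with one row per included trial: identifiers and labels,
#'   `peak_dz`, `t_peak_s`, `auc`, `curve_start_s`, `curve_end_s`, and for
#'   looming trials `mean_baseline`, `mean_5_8`, `mean_post`.
#' @export
trial_metrics <- function(trials, ignore_fraction = NULL) {
  spec <- attr(trials, "spec")
  stopifnot(inherits(spec, "fp_alignment_spec"))
  paradigm <- spec$paradigm
  ignore_fraction <- ignore_fraction %||% if (paradigm == "social") 0.05 else 0.10
  inc <- included_trials(trials)

  rows <- lapply(seq_len(nrow(inc)), function(i) {
    rt <- inc$rel_time[[i]]; dz <- inc$dz[[i]]
    curve <- select_curve(rt, dz, paradigm)
    pk <- detect_peak(rt, dz, curve, ignore_fraction)
    out <- tibble::tibble(
      subject_id = inc$subject_id[i],
      sensor_id = inc$sensor_id[i],
      trial_idx = inc$trial_idx[i],
      sex = inc$sex[i],
      familiarity = inc$familiarity[i],
      response_category = inc$response_category[i],
      peak_dz = if (is.null(pk)) NA_real_ else pk$peak_dz,
      t_peak_s = if (is.null(pk)) NA_real_ else pk$t_peak,
      auc = compute_auc(rt, dz, curve),
      curve_start_s = curve$start_s,
      curve_end_s = curve$end_s
    )
    if (paradigm == "looming") {
      em <- epoch_means(rt, dz, spec$baseline_window)
      out$mean_baseline <- em$baseline
      out$mean_5_8 <- em$loom
      out$mean_post <- em$post
    }
    out
  })
  dplyr::bind_rows(rows)
}
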