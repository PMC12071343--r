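#' Pair neuron and astrocyte trials into coupling points
#'
#' Builds the per-trial scatter underlying the neuron-astrocyte coupling
#' regression. The neuron (slow red sensor) value is plotted on x, the
#' astrocyte (fast green sensor) on y. Three pairing modes:
#'
#' * `"peak_anchored"` (social): x is the neuron's peak \eqn{\Delta z}; y is
#'   the astrocyte \eqn{\Delta z} at the *same time point* (nearest sample to
#'   the neuron's time of peak; both sensors share one acquisition clock, so
#'   no interpolation). Trials without a detected neuron peak are skipped.
#' * `"epoch_mean"` (looming): each coordinate is the sensor's mean z over
#'   5--8 s minus its baseline mean over -5 to 0 s, i.e. the mean
#'   \eqn{\Delta z} of the full-expansion epoch.
#' * `"peak_peak"`: each coordinate is the sensor's own detected peak
#'   \eqn{\Delta z}. This is the mode used for ground-truth recovery of a
#'   simulated coupling slope: unlike `"peak_anchored"`, it does not
#'   attenuate the slope when the two sensors peak at different times.
#'
#' @param neuron_trials,astro_trials `fp_trials` tables of the slow and fast
#'   sensor for the same events (run [apply_qc()] first). Trials are matched
#'   by `trial_idx`; only trials included for both sensors are paired.
#' @param mode pairing mode, see above.
#' @param ignore_fraction forwarded to [detect_peak()] for peak-based modes.
#' @return tibble of class `fp_coupling_points`: `trial_idx`, `subject_id`,
#'   labels, `neuron_dz`, `astro_dz`, `pairing_mode`, and `skip_reason`
#'   (`NA` for usable points).
#' @export
pair_trials <- function(neuron_trials, astro_trials,
                        mode = c("peak_anchored", "epoch_mean", "peak_peak"),
                        ignore_fraction = NULL) {
  mode <- match.arg(mode)
  spec <- attr(neuron_trials, "spec")
  stopifnot(inherits(spec, "fp_alignment_spec"))
  paradigm <- spec$paradigm
  ignore_fraction <- ignore_fraction %||% if (paradigm == "social") 0.05 else 0.10

  nt <- included_trials(neuron_trials)
  at <- included_trials(astro_trials)
  common <- intersect(nt$trial_idx, at$trial_idx)
  nt <- nt[match(common, nt$trial_idx), , drop = FALSE]
  at <- at[match(common, at$trial_idx), , drop = FALSE]

  rows <- lapply(seq_along(common), function(i) {
    rt <- nt$rel_time[[i]]
    ndz <- nt$dz[[i]]; adz <- at$dz[[i]]
    x <- y <- NA_real_; skip <- NA_character_
    if (mode == "epoch_mean") {
      x <- mean(ndz[rt >= 5 & rt <= 8])
      y <- mean(adz[rt >= 5 & rt <= 8])
      if (!any(rt >= 5 & rt <= 8)) skip <- "window_uncovered"
    } else {
      ncurve <- select_curve(rt, ndz, paradigm)
      npk <- detect_peak(rt, ndz, ncurve, ignore_fraction)
      if (is.null(npk)) {
        skip <- "no_neuron_peak"
      } else if (mode == "peak_anchored") {
        x <- npk$peak_dz
        y <- adz[which.min(abs(rt - npk$t_peak))]
      } else {
        acurve <- select_curve(rt, adz, paradigm)
        apk <- detect_peak(rt, adz, acurve, ignore_fraction)
        if (is.null(apk)) {
          skip <- "no_astro_peak"
        } else {
          x <- npk$peak_dz
          y <- apk$peak_dz
        }
      }
    }
    tibble::tibble(trial_idx = common[i],
                   subject_id = nt$subject_id[i],
                   sex = nt$sex[i],
                   familiarity = nt$familiarity[i],
                   response_category = nt$response_category[i],
                   neuron_dz = x, astro_dz = y,
                   pairing_mode = mode, skip_reason = skip)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fp_coupling_points", class(out))
  out
}

#' @rdname pair_trials
#' @export
pair_social <- function(neuron_trials, astro_trials, ignore_fraction = 0.05) {
  pair_trials(neuron_trials, astro_trials, "peak_anchored", ignore_fraction)
}

#' @rdname pair_trials
#' @export
pair_looming <- function(neuron_trials, astro_trials) {
  pair_trials(neuron_trials, astro_trials, "epoch_mean")
}

#' Fit the coupling regression
#'
#' Ordinary least squares of astrocyte on neuron \eqn{\Delta z} over the
#' pooled per-trial points of one condition: `y = a x + b`, with the
#' coefficient of determination and the two-sided p-value for slope != 0
#' (t distribution, n - 2 degrees of freedom).
#'
#' @param points an `fp_coupling_points` table (rows with a `skip_reason` are
#'   dropped) or a data frame with `neuron_dz` / `astro_dz` columns.
#' @return an object of class `fp_coupling_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n_points`.
#' @export
fit_coupling <- function(points) {
  pts <- points
  if (!is.null(pts[["skip_reason"]]))
    pts <- pts[is.na(pts[["skip_reason"]]), , drop = FALSE]
  x <- pts$neuron_dz; y <- pts$astro_dz
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_fc(sprintf("coupling fit needs at least 3 points (got %d)", n))
  if (stats::var(x) == 0) stop_fc("zero variance in predictor (neuron_dz)")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning on exact data
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_points = n),
            class = "fp_coupling_fit")
}

#' @export
print.fp_coupling_fit <- function(x, ...) {
  cat(sprintf("<fp_coupling_fit> y = %.3gx %+.3g, R^2 = %.3g, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n_points))
  invisible(x)
}
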