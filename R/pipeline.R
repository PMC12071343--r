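#' Run the full analysis chain on one session
#'
#' Convenience wrapper: preprocess both sensors, extract and QC event-locked
#' trials, compute per-trial metrics, and (when both sensors yield trials)
#' the coupling points and fit for the paradigm's standard pairing
#' (peak-anchored for social, epoch-mean for looming).
#'
#' @param recording an `fp_recording` (or an `fp_session`, whose events are
#'   then used automatically).
#' @param events an `fp_events` table (ignored when a session is given).
#' @param paradigm `"social"` or `"looming"`.
#' @param spec optional [alignment_spec()] override.
#' @param ... passed to [preprocess_recording()] (polynomial order, cutoff,
#'   basal window, ...).
#' @return list with `ztraces`, `trials` (per sensor, QC applied),
#'   `metrics` (per sensor), `points`, `fit` (`NULL` when fewer than 3
#'   usable points).
#' @export
analyze_session <- function(recording, events = NULL,
                            paradigm = c("social", "looming"),
                            spec = NULL, ...) {
  if (inherits(recording, "fp_session")) {
    events <- recording$events
    paradigm <- recording$truth$paradigm
    recording <- recording$recording
  } else {
    paradigm <- match.arg(paradigm)
  }
  spec <- spec %||% alignment_spec(paradigm)
  zt <- preprocess_session(recording, ...)
  trials <- lapply(zt, function(z) apply_qc(extract_trials(z, events, spec)))
  metrics <- lapply(trials, trial_metrics)
  points <- NULL; fit <- NULL
  if (nrow(included_trials(trials$slow)) > 0 &&
      nrow(included_trials(trials$fast)) > 0) {
    mode <- if (paradigm == "social") "peak_anchored" else "epoch_mean"
    points <- pair_trials(trials$slow, trials$fast, mode)
    usable <- sum(is.na(points$skip_reason))
    if (usable >= 3 && stats::var(points$neuron_dz[is.na(points$skip_reason)]) > 0)
      fit <- fit_coupling(points)
  }
  list(ztraces = zt, trials = trials, metrics = metrics,
       points = points, fit = fit)
}
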