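#' Alignment and quality-control specification
#'
#' Window and exclusion parameters for cutting a z-trace into event-locked
#' trials. The paradigm defaults follow the standard analysis windows:
#' social sniffs are extracted from -8 to +5 s around sniff initiation with a
#' -8 to -3 s baseline (the baseline precedes the mouse-initiated approach);
#' looming stimuli from -5 to +15 s around disc appearance with a -5 to 0 s
#' baseline.
#'
#' Quality control (social): bouts shorter than `min_bout_s` (1 s) are
#' dropped; subjects whose qualifying-event count is below
#' `min_events_per_subject` (4, i.e. a total count of 3 or fewer excludes the
#' mouse) lose all trials; any baseline sample deviating from the
#' baseline-window mean by strictly more than `baseline_irregularity_z`
#' (0.2 z) excludes the trial; and at most `max_trials_per_subject` (5,
#' chronologically first) are retained per subject and condition. Looming
#' trials apply only the baseline-irregularity rule.
#'
#' @param paradigm `"social"` or `"looming"`.
#' @param extract_window,baseline_window seconds relative to event start;
#'   baseline must lie within the extraction window.
#' @param min_bout_s,min_events_per_subject,baseline_irregularity_z,max_trials_per_subject
#'   QC parameters; see Details.
#' @return an object of class `fp_alignment_spec`.
#' @export
alignment_spec <- function(paradigm = c("social", "looming"),
                           extract_window = NULL,
                           baseline_window = NULL,
                           min_bout_s = NULL,
                           min_events_per_subject = NULL,
                           baseline_irregularity_z = 0.2,
                           max_trials_per_subject = NULL) {
  paradigm <- match.arg(paradigm)
  if (paradigm == "social") {
    extract_window <- extract_window %||% c(-8, 5)
    baseline_window <- baseline_window %||% c(-8, -3)
    min_bout_s <- min_bout_s %||% 1
    min_events_per_subject <- min_events_per_subject %||% 4L
    max_trials_per_subject <- max_trials_per_subject %||% 5L
  } else {
    extract_window <- extract_window %||% c(-5, 15)
    baseline_window <- baseline_window %||% c(-5, 0)
    min_bout_s <- min_bout_s %||% 0
    min_events_per_subject <- min_events_per_subject %||% 0L
    max_trials_per_subject <- max_trials_per_subject %||% Inf
  }
  if (!(extract_window[1] < 0 && extract_window[2] > 0))
    stop_fc("extract_window must straddle the event start (t_min < 0 < t_max)")
  if (baseline_window[1] < extract_window[1] || baseline_window[2] > extract_window[2])
    stop_fc("baseline_window must lie within extract_window")
  structure(list(paradigm = paradigm,
                 extract_window = extract_window,
                 baseline_window = baseline_window,
                 min_bout_s = min_bout_s,
                 min_events_per_subject = min_events_per_subject,
                 baseline_irregularity_z = baseline_irregularity_z,
                 max_trials_per_subject = max_trials_per_subject),
            class = "fp_alignment_spec")
}

#' Cut a z-trace into event-locked trials
#'
#' For every anchoring event (sniff bouts for the social paradigm, stimulus
#' onsets for looming) the z-score segment over the extraction window is
#' pulled out, the mean of its own baseline window is subtracted (giving the
#' \eqn{\Delta z} series `dz`), and the trial is stored with its relative
#' time axis (0 = event start). Events whose window would run outside the
#' recording are kept with `qc_status = "excluded:window_out_of_range"`.
#' No other QC happens here; see [apply_qc()].
#'
#' @param ztrace an `fp_ztrace`.
#' @param events an `fp_events` table.
#' @param spec an `fp_alignment_spec`.
#' @return a tibble of class `fp_trials`: one row per trial with event
#'   metadata, `bout_s`, list-columns `rel_time` and `dz`, and `qc_status`.
#' @export
extract_trials <- function(ztrace, events, spec) {
  stopifnot(inherits(ztrace, "fp_ztrace"), inherits(spec, "fp_alignment_spec"))
  anchor_type <- if (spec$paradigm == "social") "sniff" else "loom_stimulus"
  ev <- events[events$event_type == anchor_type, , drop = FALSE]
  ev <- ev[order(ev$start_s), , drop = FALSE]

  fs <- ztrace$sampling_rate
  i_lo <- as.integer(round(spec$extract_window[1] * fs))
  i_hi <- as.integer(round(spec$extract_window[2] * fs))
  rel_time <- (i_lo:i_hi) / fs
  base_idx <- which(rel_time >= spec$baseline_window[1] &
                    rel_time <= spec$baseline_window[2])

  rows <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- nearest_index(ztrace$time, ev$start_s[i])
    idx <- i0 + (i_lo:i_hi)
    if (idx[1] < 1L || idx[length(idx)] > length(ztrace$z)) {
      dz <- list(rep(NA_real_, length(rel_time)))
      status <- "excluded:window_out_of_range"
    } else {
      seg <- ztrace$z[idx]
      dz <- list(seg - mean(seg[base_idx]))
      status <- "included"
    }
    tibble::tibble(
      subject_id = ev$subject_id[i],
      sensor_id = ztrace$sensor_id,
      trial_idx = i,
      event_type = ev$event_type[i],
      start_s = ev$start_s[i],
      stop_s = ev$stop_s[i],
      bout_s = ev$stop_s[i] - ev$start_s[i],
      sex = ev$sex[i],
      familiarity = ev$familiarity[i],
      response_category = ev$response_category[i],
      rel_time = list(rel_time),
      dz = dz,
      qc_status = status
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  attr(out, "baseline_idx") <- base_idx
  class(out) <- c("fp_trials", class(out))
  out
}

#' Apply trial inclusion / exclusion rules
#'
#' Exclusion reasons are evaluated in a fixed order and each excluded trial
#' carries exactly one primary reason:
#' `min_bout` (social bout shorter than the minimum), then `min_events`
#' (subject-condition with too few qualifying bouts), then
#' `baseline_irregularity` (any baseline sample deviating from the baseline
#' mean by strictly more than the threshold; a deviation exactly at the
#' threshold passes), then `trial_cap` (only the chronologically first
#' `max_trials_per_subject` surviving trials are kept per subject and
#' condition). The operation is idempotent and never errors on content.
#'
#' @param trials an `fp_trials` table from [extract_trials()].
#' @param spec the `fp_alignment_spec`; defaults to the one attached to
#'   `trials`.
#' @return `trials` with refreshed `qc_status`
#'   (`"included"` or `"excluded:<reason>"`).
#' @export
apply_qc <- function(trials, spec = NULL) {
  spec <- spec %||% attr(trials, "spec")
  stopifnot(inherits(spec, "fp_alignment_spec"))
  base_idx <- attr(trials, "baseline_idx")
  status <- trials$qc_status
  fresh <- status != "excluded:window_out_of_range"
  status[fresh] <- "included"

  # 1. minimum bout duration (social)
  short <- fresh & trials$bout_s < spec$min_bout_s
  status[short] <- "excluded:min_bout"

  # 2. minimum qualifying-event count per subject-condition; qualifying means
  #    a schedulable bout of sufficient length, regardless of later exclusions
  if (spec$min_events_per_subject > 0) {
    key <- paste(trials$subject_id, trials$familiarity)
    qual <- tapply(fresh & !short, key, sum)
    few <- fresh & !short & (qual[key] < spec$min_events_per_subject)
    status[few] <- "excluded:min_events"
  } else {
    few <- rep(FALSE, nrow(trials))
  }

  # 3. baseline irregularity: dz within the baseline window already measures
  #    deviation from the baseline-window mean
  candidate <- fresh & !short & !few
  irr <- candidate & vapply(trials$dz, function(d) {
    any(abs(d[base_idx]) > spec$baseline_irregularity_z)
  }, logical(1))
  status[irr] <- "excluded:baseline_irregularity"

  # 4. trial cap: chronologically first k surviving trials per subject-condition
  if (is.finite(spec$max_trials_per_subject)) {
    surv <- which(candidate & !irr)
    key <- paste(trials$subject_id, trials$familiarity)[surv]
    ord <- surv[order(trials$start_s[surv])]
    kord <- paste(trials$subject_id, trials$familiarity)[ord]
    rank_in_grp <- stats::ave(seq_along(ord), kord, FUN = seq_along)
    over <- ord[rank_in_grp > spec$max_trials_per_subject]
    status[over] <- "excluded:trial_cap"
  }

  trials$qc_status <- status
  trials
}

#' Keep only QC-included trials
#' @param trials an `fp_trials` table.
#' @return the included subset (attributes preserved).
#' @export
included_trials <- function(trials) {
  out <- trials[trials$qc_status == "included", , drop = FALSE]
  attr(out, "spec") <- attr(trials, "spec")
  attr(out, "baseline_idx") <- attr(trials, "baseline_idx")
  out
}

#' Write trials in long format
#'
#' One row per trial sample: subject, sensor, trial index, relative time,
#' \eqn{\Delta z}, QC status and labels.
#' @param trials an `fp_trials` table.
#' @param path CSV path.
#' @export
write_trials <- function(trials, path) {
  long <- tidyr::unnest(
    dplyr::select(trials, "subject_id", "sensor_id", "trial_idx", "sex",
                  "familiarity", "response_category", "qc_status",
                  "rel_time", "dz"),
    cols = c("rel_time", "dz"))
  names(long)[names(long) == "rel_time"] <- "rel_time_s"
  readr::write_csv(long, path)
  invisible(path)
}
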