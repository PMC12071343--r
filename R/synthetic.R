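#' Generate a synthetic social-interaction session
#'
#' Renders a four-channel recording (two sensor channels plus their isosbestic
#' controls) and the matching sniff-bout event table from a ground truth built
#' with [simulation_truth()]. Signal channels receive photobleaching, the
#' shared motion artifacts, white noise, and event-locked transients; the
#' isosbestic channels receive the same bleaching and the *same* motion
#' waveform with independent noise but no transients, so that the isosbestic
#' subtraction step cancels motion exactly up to noise.
#'
#' The neuron (slow red sensor) transient amplitude of event \eqn{i} is
#' `truth$event_amplitudes[i]`; the astrocyte (fast green sensor) amplitude is
#' `coupling_slope * a_i + coupling_intercept + N(0, coupling_noise_sd)`.
#' Both are true peak \eqn{\Delta z} values of the processed trace (see
#' [simulation_truth()] for the calibration).
#'
#' @param truth an `fp_truth` from [simulation_truth()] with
#'   `paradigm = "social"`.
#' @return an `fp_session`: list with `recording` ([raw_recording()]),
#'   `events` (sniff [event_table()]), and `truth` (the input truth with the
#'   realized astrocyte amplitudes appended as `astro_amplitudes`).
#' @examples
#' s <- generate_social_session(simulation_truth("social", duration = 120,
#'                                               n_events = 5, seed = 2))
#' s$recording
#' @export
generate_social_session <- function(truth) {
  stopifnot(inherits(truth, "fp_truth"))
  if (truth$paradigm != "social")
    stop_fc("`truth` was built for the looming paradigm; use generate_looming_session()")
  session_from_truth(truth)
}

#' Generate a synthetic looming-shadow session
#'
#' As [generate_social_session()], but the event table describes looming
#' stimuli: each stimulus row spans the 8 s presentation (3 s small disc, 2 s
#' expansion, 3 s hold), labeled with the simulated behavioral response
#' category and latency, and is accompanied by a scored `run` or `freeze`
#' behavior row when a response occurred. Transients are placed
#' `truth$transient_onset_rel_s` after stimulus onset (default 3.5 s, during
#' shadow expansion).
#'
#' @inheritParams generate_social_session
#' @return an `fp_session`; see [generate_social_session()].
#' @export
generate_looming_session <- function(truth) {
  stopifnot(inherits(truth, "fp_truth"))
  if (truth$paradigm != "looming")
    stop_fc("`truth` was built for the social paradigm; use generate_social_session()")
  session_from_truth(truth)
}

# shared renderer for both paradigms
session_from_truth <- function(truth) {
  fs <- truth$sampling_rate
  n <- as.integer(round(truth$duration * fs))
  tt <- seq_len(n) / fs
  sched <- truth$event_schedule

  set.seed(truth$seed + 15485863L)

  amp_n <- truth$event_amplitudes
  amp_a <- truth$coupling_slope * amp_n + truth$coupling_intercept +
    stats::rnorm(length(amp_n), 0, truth$coupling_noise_sd)

  # transient onsets: event start (social) or fixed offset into the stimulus
  t_on <- sched$onset_s
  if (truth$paradigm == "looming") t_on <- t_on + truth$transient_onset_rel_s

  k_slow <- geci_kernel(truth$kinetics$slow, fs)
  k_fast <- geci_kernel(truth$kinetics$fast, fs)

  # calibration: raw units per unit delta-z (see simulation_truth docs)
  sigma_scale <- if (truth$noise_sd > 0) sqrt(2) * truth$noise_sd else 1
  att_slow <- filter_attenuation(k_slow, fs, truth$filter_cutoff_hz)
  att_fast <- filter_attenuation(k_fast, fs, truth$filter_cutoff_hz)

  add_transients <- function(amps, kern, att) {
    x <- numeric(n)
    for (i in seq_along(amps)) {
      i0 <- as.integer(round(t_on[i] * fs))
      idx <- i0 + seq_along(kern) - 1L
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + amps[i] * sigma_scale / att * kern[keep]
    }
    x
  }

  bleach_curve <- truth$bleach$amplitude[1] * exp(-tt / truth$bleach$tau[1]) +
    truth$bleach$amplitude[2] * exp(-tt / truth$bleach$tau[2])

  motion_wave <- numeric(n)
  if (nrow(truth$motion) > 0) {
    for (i in seq_len(nrow(truth$motion))) {
      i0 <- as.integer(round(truth$motion$onset_s[i] * fs))
      len <- max(2L, as.integer(round(truth$motion$duration_s[i] * fs)))
      idx <- i0 + seq_len(len) - 1L
      keep <- idx >= 1L & idx <= n
      bump <- truth$motion$amplitude[i] *
        (1 - cos(2 * pi * seq_len(len) / (len + 1))) / 2
      motion_wave[idx[keep]] <- motion_wave[idx[keep]] + bump[keep]
    }
  }

  glitch_wave <- list(sig_fast = numeric(n), iso_fast = numeric(n),
                      sig_slow = numeric(n), iso_slow = numeric(n))
  if (!is.null(truth$glitches) && nrow(truth$glitches) > 0) {
    box_att <- vapply(truth$glitches$duration_s, function(d) {
      filter_attenuation(rep(1, max(2L, as.integer(round(d * fs)))),
                         fs, truth$filter_cutoff_hz)
    }, numeric(1))
    for (i in seq_len(nrow(truth$glitches))) {
      ch <- truth$glitches$channel[i]
      i0 <- as.integer(round(truth$glitches$onset_s[i] * fs))
      len <- max(2L, as.integer(round(truth$glitches$duration_s[i] * fs)))
      idx <- i0 + seq_len(len) - 1L
      idx <- idx[idx >= 1L & idx <= n]
      glitch_wave[[ch]][idx] <- glitch_wave[[ch]][idx] +
        truth$glitches$amplitude_dz[i] * sigma_scale / box_att[i]
    }
  }

  channel <- function(ch, transients) {
    truth$baseline_level + truth$bleach_channel_scale[[ch]] * bleach_curve +
      motion_wave + transients + glitch_wave[[ch]] +
      stats::rnorm(n, 0, truth$noise_sd)
  }

  data <- tibble::tibble(
    time_s   = tt,
    sig_fast = channel("sig_fast", add_transients(amp_a, k_fast, att_fast)),
    iso_fast = channel("iso_fast", 0),
    sig_slow = channel("sig_slow", add_transients(amp_n, k_slow, att_slow)),
    iso_slow = channel("iso_slow", 0)
  )

  rec <- raw_recording(data, sampling_rate = fs,
                       subject_id = truth$subject_id, sex = truth$sex)

  if (truth$paradigm == "social") {
    events <- event_table(tibble::tibble(
      subject_id = truth$subject_id,
      event_type = "sniff",
      start_s = sched$onset_s,
      stop_s = sched$offset_s,
      sex = truth$sex,
      familiarity = truth$familiarity,
      response_category = "n/a",
      latency_s = NA_real_
    ))
  } else {
    stim <- tibble::tibble(
      subject_id = truth$subject_id,
      event_type = "loom_stimulus",
      start_s = sched$onset_s,
      stop_s = sched$offset_s,
      sex = truth$sex,
      familiarity = "n/a",
      response_category = sched$response_category,
      latency_s = sched$latency_s
    )
    resp <- sched[sched$response_category != "none", , drop = FALSE]
    behav <- tibble::tibble(
      subject_id = truth$subject_id,
      event_type = resp$response_category,
      start_s = resp$onset_s + resp$latency_s,
      stop_s = resp$onset_s + resp$latency_s +
        ifelse(resp$response_category == "freeze", resp$freeze_duration_s, 1.5),
      sex = truth$sex,
      familiarity = "n/a",
      response_category = "n/a",
      latency_s = NA_real_
    )
    events <- event_table(dplyr::arrange(dplyr::bind_rows(stim, behav), .data$start_s))
  }

  truth$astro_amplitudes <- amp_a
  structure(list(recording = rec, events = events, truth = truth),
            class = "fp_session")
}

#' @export
print.fp_session <- function(x, ...) {
  cat(sprintf("<fp_session> %s: %d samples @ %g Hz, %d event rows\n",
              x$truth$paradigm, nrow(x$recording$data),
              x$recording$sampling_rate, nrow(x$events)))
  invisible(x)
}
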