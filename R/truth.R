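#' Ground truth for a simulated dual-sensor photometry session
#'
#' Builds the complete parameter set ("truth") from which
#' [generate_social_session()] or [generate_looming_session()] renders a
#' synthetic recording plus behavioral event table. The truth carries
#' everything a downstream parameter-recovery test needs: the event schedule,
#' the per-event neuron amplitudes, the linear neuron-to-astrocyte coupling,
#' sensor kinetics, photobleaching, shared motion artifacts, and noise.
#'
#' Amplitudes are expressed as true peak \eqn{\Delta z} of the processed trace
#' (polynomial detrend, isosbestic subtraction, zero-phase low-pass at
#' `filter_cutoff_hz`, z-scoring against whole-session basal statistics of the
#' corrected trace). The generator converts them to raw fluorescence units by
#' dividing by the numerically measured attenuation of the sensor kernel under
#' that filter, so that what the analysis chain should recover is exactly the
#' amplitude written here.
#'
#' @param paradigm `"social"` (sniff bouts) or `"looming"` (shadow stimuli).
#' @param sampling_rate samples per second of the rendered recording (Hz).
#'   100 Hz keeps desk-scale tests fast; the hardware rate is 1 kHz.
#' @param duration session length in seconds (10 min by default).
#' @param n_events number of sniff bouts (social) or stimuli (looming;
#'   must be 6--8).
#' @param event_onsets,event_durations optional explicit schedule (seconds).
#'   Looming durations are fixed at the 8 s stimulus (3 s disc, 2 s
#'   expansion, 3 s hold) and may not be overridden.
#' @param event_amplitudes per-event true peak \eqn{\Delta z} of the neuron
#'   (slow red sensor). Default: drawn uniformly from `amplitude_range`.
#' @param amplitude_range range for drawn amplitudes; the default matches the
#'   0.1--0.5 \eqn{\Delta z} order of magnitude of in vivo transients.
#' @param coupling_slope,coupling_intercept,coupling_noise_sd linear map from
#'   neuron amplitude to astrocyte (fast green sensor) amplitude:
#'   `a_astro = slope * a_neuron + intercept + N(0, noise_sd)`.
#' @param kinetics list with elements `fast` and `slow`, each
#'   `c(rise, decay)` time constants in seconds of the
#'   difference-of-exponentials transient kernel.
#' @param noise_sd white measurement noise, raw fluorescence units,
#'   independent per channel.
#' @param baseline_level static fluorescence offset, raw units.
#' @param bleach list `amplitude = c(a1, a2)`, `tau = c(t1, t2)` (seconds):
#'   double-exponential photobleaching `a1 exp(-t/t1) + a2 exp(-t/t2)`,
#'   scaled per channel by `bleach_channel_scale`.
#' @param bleach_channel_scale named multipliers for channels
#'   `sig_fast`, `iso_fast`, `sig_slow`, `iso_slow`.
#' @param motion tibble/data.frame with `onset_s`, `duration_s`, `amplitude`:
#'   raised-cosine artifacts added identically to every channel (the
#'   isosbestic subtraction should cancel them). `NULL` draws a default set;
#'   use `motion = "none"` for no artifacts.
#' @param glitches optional tibble with `channel`, `onset_s`, `duration_s`,
#'   `amplitude_dz`: boxcar artifacts injected into a single channel
#'   (calibrated to post-chain \eqn{\Delta z} units) for testing the
#'   baseline-irregularity rule.
#' @param transient_onset_rel_s looming only: transient onset relative to
#'   stimulus (disc) onset; 3.5 s places it during shadow expansion so the
#'   response peaks in the 5--8 s full-expansion epoch.
#' @param response_probs looming only: probabilities of the `run`, `freeze`,
#'   `none` behavioral categories (defaults match the pooled published trial
#'   counts 48/20/16 of 84).
#' @param filter_cutoff_hz low-pass cutoff assumed for amplitude calibration.
#' @param subject_id,sex,familiarity labels written into the event table.
#' @param seed integer seed; the schedule, amplitudes, labels, and the
#'   generator's noise draws are all deterministic given the truth.
#'
#' @return an object of class `fp_truth` (a named list).
#' @seealso [generate_social_session()], [generate_looming_session()]
#' @export
simulation_truth <- function(paradigm = c("social", "looming"),
                             sampling_rate = 100,
                             duration = 600,
                             n_events = NULL,
                             event_onsets = NULL,
                             event_durations = NULL,
                             event_amplitudes = NULL,
                             amplitude_range = c(0.15, 0.45),
                             coupling_slope = 0.5,
                             coupling_intercept = 0,
                             coupling_noise_sd = 0.05,
                             kinetics = list(fast = c(rise = 0.1, decay = 0.6),
                                             slow = c(rise = 0.3, decay = 1.5)),
                             noise_sd = 1,
                             baseline_level = 100,
                             bleach = list(amplitude = c(10, 5),
                                           tau = c(300, 1200)),
                             bleach_channel_scale = c(sig_fast = 1, iso_fast = 0.8,
                                                      sig_slow = 1.1, iso_slow = 0.7),
                             motion = NULL,
                             glitches = NULL,
                             transient_onset_rel_s = 3.5,
                             response_probs = c(run = 48, freeze = 20, none = 16) / 84,
                             filter_cutoff_hz = 0.3,
                             subject_id = "sim01",
                             sex = "female",
                             familiarity = "unfamiliar",
                             seed = 1L) {
  paradigm <- match.arg(paradigm)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_fc("`noise_sd` must be >= 0")
  for (s in c("fast", "slow")) {
    k <- kinetics[[s]]
    if (any(k <= 0)) stop_fc(sprintf("kinetic time constants for sensor '%s' must be > 0", s))
    if (k[["rise"]] >= k[["decay"]])
      stop_fc(sprintf("sensor '%s': rise time constant must be < decay time constant", s))
  }
  if (any(unlist(bleach$tau) <= 0)) stop_fc("bleach time constants must be > 0")

  rng <- local({
    set.seed(as.integer(seed))
    list(
      onsets    = function(n, lo, hi) sort(stats::runif(n, lo, hi)),
      durations = function(n) stats::rlnorm(n, meanlog = log(1.8), sdlog = 0.55),
      amps      = function(n) stats::runif(n, amplitude_range[1], amplitude_range[2]),
      cats      = function(n) sample(names(response_probs), n, replace = TRUE,
                                     prob = response_probs),
      lat       = function(n, mean, sd) {
        x <- stats::rnorm(n, mean, sd)
        while (any(bad <- x < 0.5 | x >= 7.9)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
        x
      },
      frz       = function(n) {
        x <- stats::rnorm(n, 17, 8)
        while (any(bad <- x < 2)) x[bad] <- stats::rnorm(sum(bad), 17, 8)
        x
      }
    )
  })

  if (paradigm == "social") {
    n_events <- n_events %||% 30L
    if (is.null(event_onsets)) {
      # even spacing with enough margin for the [-8, +5] s alignment window
      event_onsets <- seq(15, duration - 15, length.out = n_events)
    }
    n_events <- length(event_onsets)
    event_durations <- event_durations %||% rng$durations(n_events)
    support <- kernel_support(kinetics$slow)
    if (any(diff(event_onsets) <= 0))
      stop_fc("event onsets must be strictly increasing")
    if (any(diff(event_onsets) < support))
      stop_fc(sprintf(
        "events overlap: onsets closer than the transient kernel support (%.1f s)",
        support))
    schedule <- tibble::tibble(
      onset_s  = event_onsets,
      offset_s = event_onsets + event_durations,
      label    = "sniff"
    )
  } else {
    n_events <- n_events %||% 7L
    if (n_events < 6L || n_events > 8L)
      stop_fc(sprintf("looming sessions use 6-8 stimulus presentations (got %d)", n_events))
    if (is.null(event_onsets)) {
      event_onsets <- seq(40, duration - 20, length.out = n_events)
    }
    n_events <- length(event_onsets)
    if (any(diff(event_onsets) <= 0))
      stop_fc("event onsets must be strictly increasing")
    if (any(diff(event_onsets) < 60))
      stop_fc("looming stimuli must be presented at >= 1 min intervals; schedule does not fit")
    if (utils::tail(event_onsets, 1) + 8 > duration || event_onsets[1] < 0)
      stop_fc("looming schedule does not fit within the session duration")
    if (!is.null(event_durations))
      stop_fc("looming stimulus duration is fixed at 8 s and cannot be overridden")
    cats <- rng$cats(n_events)
    lat <- rep(NA_real_, n_events)
    lat[cats == "run"]    <- rng$lat(sum(cats == "run"), 4.3, 0.9)
    lat[cats == "freeze"] <- rng$lat(sum(cats == "freeze"), 5.3, 1.1)
    frz <- rep(NA_real_, n_events)
    frz[cats == "freeze"] <- rng$frz(sum(cats == "freeze"))
    schedule <- tibble::tibble(
      onset_s  = event_onsets,
      offset_s = event_onsets + 8,
      label    = "loom_stimulus",
      response_category = cats,
      latency_s = lat,
      freeze_duration_s = frz
    )
  }
  if (any(schedule$offset_s > duration) || any(schedule$onset_s < 0))
    stop_fc("events must fit within the session duration")

  event_amplitudes <- event_amplitudes %||% rng$amps(n_events)
  if (length(event_amplitudes) != n_events)
    stop_fc("`event_amplitudes` must have one value per event")

  if (is.null(motion)) {
    set.seed(as.integer(seed) + 104729L)
    motion <- tibble::tibble(
      onset_s    = sort(stats::runif(6, 5, duration - 5)),
      duration_s = stats::runif(6, 0.3, 0.6),
      amplitude  = 5 * max(noise_sd, 1)
    )
  } else if (identical(motion, "none")) {
    motion <- tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                             amplitude = numeric())
  } else {
    motion <- tibble::as_tibble(motion)
  }
  if (!is.null(glitches)) glitches <- tibble::as_tibble(glitches)

  structure(list(
    paradigm = paradigm,
    sampling_rate = sampling_rate,
    duration = duration,
    event_schedule = schedule,
    event_amplitudes = event_amplitudes,
    coupling_slope = coupling_slope,
    coupling_intercept = coupling_intercept,
    coupling_noise_sd = coupling_noise_sd,
    kinetics = kinetics,
    noise_sd = noise_sd,
    baseline_level = baseline_level,
    bleach = bleach,
    bleach_channel_scale = bleach_channel_scale,
    motion = motion,
    glitches = glitches,
    transient_onset_rel_s = transient_onset_rel_s,
    response_probs = response_probs,
    filter_cutoff_hz = filter_cutoff_hz,
    subject_id = subject_id,
    sex = sex,
    familiarity = familiarity,
    seed = as.integer(seed)
  ), class = "fp_truth")
}

#' @export
print.fp_truth <- function(x, ...) {
  cat(sprintf("<fp_truth> %s session: %.0f s @ %g Hz, %d events, coupling %.3g x + %.3g\n",
              x$paradigm, x$duration, x$sampling_rate,
              nrow(x$event_schedule), x$coupling_slope, x$coupling_intercept))
  invisible(x)
}

# --- transient kernel ------------------------------------------------------

#' Difference-of-exponentials transient kernel
#'
#' Unit-peak impulse shape of a calcium indicator transient,
#' `exp(-t/decay) - exp(-t/rise)` normalized so its maximum is 1, sampled at
#' `sampling_rate` until it falls below 1% of the peak.
#'
#' @param kinetics `c(rise, decay)` time constants (s), rise < decay.
#' @param sampling_rate Hz.
#' @return numeric vector starting at t = 0.
#' @keywords internal
geci_kernel <- function(kinetics, sampling_rate) {
  support <- kernel_support(kinetics)
  t <- seq(0, support, by = 1 / sampling_rate)
  k <- exp(-t / kinetics[["decay"]]) - exp(-t / kinetics[["rise"]])
  k / max(k)
}

# time for the unit-peak kernel to fall below 1% of its maximum
kernel_support <- function(kinetics) {
  tr <- kinetics[["rise"]]; td <- kinetics[["decay"]]
  t_peak <- log(td / tr) * tr * td / (td - tr)
  t_peak + td * log(100)
}

# peak attenuation of a waveform under the zero-phase low-pass used by the
# analysis chain; used to calibrate raw injection amplitudes so that the
# post-chain peak delta-z equals the amplitude written in the truth
filter_attenuation <- function(wave, sampling_rate, cutoff_hz) {
  pad <- as.integer(10 * sampling_rate)
  x <- c(numeric(pad), wave, numeric(pad))
  max(lowpass(x, sampling_rate, cutoff_hz)) / max(wave)
}
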