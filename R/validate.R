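#' Ground-truth recovery experiments
#'
#' Each experiment simulates sessions with known parameters, runs the full
#' analysis chain (simulate, preprocess, align, QC, metrics, couple), and
#' reports how well the chain recovers the injected ground truth. They are
#' the package's built-in validation battery; the methods vignette documents
#' the study conditions each one uses.
#'
#' @name recovery-experiments
NULL

#' @describeIn recovery-experiments Recovery of injected transient peak
#'   amplitudes. One social session per amplitude level (default desk-scale
#'   conditions: 100 Hz, 200 transients of identical amplitude at 20 s
#'   spacing, default noise); reports the mean recovered peak
#'   \eqn{\Delta z} and its relative error per level.
#' @param amplitudes amplitude levels (true peak \eqn{\Delta z}).
#' @param n_trials trials per level.
#' @param sampling_rate Hz.
#' @param seed integer seed.
#' @return `recover_peak_amplitude`: tibble with `amplitude`,
#'   `mean_recovered`, `relative_error`.
#' @export
recover_peak_amplitude <- function(amplitudes = c(0.2, 0.3, 0.4),
                                   n_trials = 200, sampling_rate = 100,
                                   seed = 1L) {
  rows <- lapply(seq_along(amplitudes), function(i) {
    a <- amplitudes[i]
    duration <- 20 * n_trials + 40
    truth <- simulation_truth(
      "social", sampling_rate = sampling_rate, duration = duration,
      n_events = n_trials,
      event_onsets = seq(20, duration - 15, length.out = n_trials),
      event_durations = rep(2, n_trials),
      event_amplitudes = rep(a, n_trials),
      seed = seed + i
    )
    s <- generate_social_session(truth)
    z <- preprocess_recording(s$recording, "slow")
    spec <- alignment_spec("social", max_trials_per_subject = Inf,
                           min_events_per_subject = 0)
    tr <- apply_qc(extract_trials(z, s$events, spec), spec)
    mets <- trial_metrics(tr)
    mean_rec <- mean(mets$peak_dz, na.rm = TRUE)
    tibble::tibble(amplitude = a, mean_recovered = mean_rec,
                   relative_error = mean_rec / a - 1)
  })
  dplyr::bind_rows(rows)
}

#' @describeIn recovery-experiments Recovery of the neuron-to-astrocyte
#'   coupling slope. Replicated long sessions at the hardware sampling rate
#'   (1 kHz, 1250 s, 50 trials, neuron amplitudes uniform on
#'   `amplitude_range`), full chain, then OLS on each sensor's own recovered
#'   peak (`pairing mode "peak_peak"`). Returns the per-replicate slopes and
#'   the mean relative bias.
#' @param coupling_slope,coupling_intercept,coupling_noise_sd true coupling.
#' @param n_replicates seeded replicates.
#' @param amplitude_range neuron amplitude range (kept >= 0.2 so every
#'   transient is well above the peak-ignore floor).
#' @return `recover_coupling_slope`: list with `slopes`, `mean_slope`,
#'   `relative_bias`.
#' @export
recover_coupling_slope <- function(coupling_slope = 0.5,
                                   coupling_intercept = 0,
                                   coupling_noise_sd = 0.05,
                                   n_replicates = 20, n_trials = 50,
                                   sampling_rate = 1000,
                                   amplitude_range = c(0.2, 0.8),
                                   seed = 1L) {
  duration <- 25 * n_trials
  spec <- alignment_spec("social", max_trials_per_subject = Inf,
                         min_events_per_subject = 0)
  slopes <- vapply(seq_len(n_replicates), function(r) {
    truth <- simulation_truth(
      "social", sampling_rate = sampling_rate, duration = duration,
      n_events = n_trials,
      event_onsets = seq(20, duration - 15, length.out = n_trials),
      event_durations = rep(2, n_trials),
      amplitude_range = amplitude_range,
      coupling_slope = coupling_slope,
      coupling_intercept = coupling_intercept,
      coupling_noise_sd = coupling_noise_sd,
      seed = seed + 1000L * r
    )
    s <- generate_social_session(truth)
    zt <- preprocess_session(s$recording)
    tr <- lapply(zt, function(z) apply_qc(extract_trials(z, s$events, spec), spec))
    pts <- pair_trials(tr$slow, tr$fast, "peak_peak")
    fit_coupling(pts)$slope
  }, numeric(1))
  list(slopes = slopes, mean_slope = mean(slopes),
       relative_bias = mean(slopes) / coupling_slope - 1)
}

#' @describeIn recovery-experiments Sensitivity and specificity of the
#'   baseline-irregularity rule. Social sessions at desk scale with boxcar
#'   glitches (default 0.8 \eqn{\Delta z}, 1 s) injected into the baseline
#'   windows of a known half of the trials; reports the fraction of glitched
#'   trials excluded for baseline irregularity (sensitivity) and the
#'   fraction of clean trials falsely excluded.
#' @param n_sessions sessions to pool.
#' @param glitch_dz glitch amplitude in post-chain \eqn{\Delta z} units.
#' @return `recover_glitch_qc`: list with `sensitivity`,
#'   `false_exclusion_rate`, `n_glitched`, `n_clean`.
#' @export
recover_glitch_qc <- function(n_sessions = 6, n_trials = 24,
                              glitch_dz = 0.8, sampling_rate = 100,
                              seed = 1L) {
  spec <- alignment_spec("social", max_trials_per_subject = Inf,
                         min_events_per_subject = 0)
  hits <- misses <- false_pos <- clean_n <- 0L
  for (s_i in seq_len(n_sessions)) {
    duration <- 20 * n_trials + 40
    onsets <- seq(20, duration - 15, length.out = n_trials)
    glitched <- seq(1, n_trials, by = 2)
    glitches <- tibble::tibble(
      channel = "sig_slow",
      onset_s = onsets[glitched] - 6,   # inside the [-8, -3] s baseline
      duration_s = 1,
      amplitude_dz = glitch_dz
    )
    truth <- simulation_truth(
      "social", sampling_rate = sampling_rate, duration = duration,
      n_events = n_trials,
      event_onsets = onsets, event_durations = rep(2, n_trials),
      glitches = glitches, seed = seed + s_i
    )
    s <- generate_social_session(truth)
    z <- preprocess_recording(s$recording, "slow")
    tr <- apply_qc(extract_trials(z, s$events, spec), spec)
    is_glitched <- tr$trial_idx %in% glitched
    excl <- tr$qc_status == "excluded:baseline_irregularity"
    hits <- hits + sum(excl & is_glitched)
    misses <- misses + sum(!excl & is_glitched)
    false_pos <- false_pos + sum(excl & !is_glitched)
    clean_n <- clean_n + sum(!is_glitched)
  }
  list(sensitivity = hits / (hits + misses),
       false_exclusion_rate = false_pos / clean_n,
       n_glitched = hits + misses, n_clean = clean_n)
}

#' @describeIn recovery-experiments Empirical type-I error of a test
#'   statistic under its null. `generator(i)` must return the arguments for
#'   `test_fn` as a list; the rejection rate at `alpha` over `n_reps`
#'   replicates is returned.
#' @param test_fn function returning a one-row stats tibble (or a list with
#'   `p_value`).
#' @param generator function of the replicate index producing null data.
#' @param n_reps replicates.
#' @param alpha nominal level.
#' @return `type_one_error`: the empirical rejection rate.
#' @export
type_one_error <- function(test_fn, generator, n_reps = 10000, alpha = 0.05,
                           seed = 1L) {
  set.seed(seed)
  rej <- vapply(seq_len(n_reps), function(i) {
    res <- do.call(test_fn, generator(i))
    p <- if (is.list(res) && !is.null(res$p_value)) res$p_value else res
    p[1] < alpha
  }, logical(1))
  mean(rej)
}
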