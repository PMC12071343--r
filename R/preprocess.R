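#' Polynomial baseline detrending
#'
#' Fits a least-squares polynomial of the given order to the whole-session
#' trace and returns the residual together with the fitted curve. This removes
#' slow photobleaching drift while leaving multi-second transients intact.
#'
#' @param trace numeric vector, raw fluorescence.
#' @param order polynomial order (default 2; 0 subtracts the mean).
#' @param time optional time axis (seconds); defaults to the sample index.
#' @return list with `detrended` and `fitted` numeric vectors.
#' @export
detrend_baseline <- function(trace, order = 2, time = NULL) {
  n <- length(trace)
  if (order < 0) stop_fc("polynomial `order` must be >= 0")
  if (n <= order + 1) stop_fc("trace length must exceed polynomial order + 1")
  time <- time %||% seq_len(n)
  if (order == 0) {
    fit <- rep(mean(trace), n)
  } else {
    # orthogonal polynomial basis keeps the normal equations well conditioned
    basis <- stats::poly(time, degree = order)
    fit <- as.numeric(qr.fitted(qr(cbind(1, basis)), trace))
  }
  list(detrended = trace - fit, fitted = fit)
}

#' Isosbestic motion correction
#'
#' Subtracts the isosbestic control trace from the sensor trace at each time
#' point. Motion artifacts and residual bleaching are shared between the two
#' excitation wavelengths and cancel; calcium-dependent fluorescence is only
#' present in the sensor channel. With `rescale = TRUE` the isosbestic trace
#' is first scaled by an ordinary least-squares fit to the signal (off by
#' default: plain pointwise subtraction).
#'
#' @param signal_trace,isosbestic_trace detrended numeric vectors of equal
#'   length.
#' @param rescale logical.
#' @return corrected numeric vector.
#' @export
motion_correct <- function(signal_trace, isosbestic_trace, rescale = FALSE) {
  if (length(signal_trace) != length(isosbestic_trace))
    stop_fc("signal and isosbestic traces must have the same length")
  if (rescale) {
    b <- stats::coef(stats::lm(signal_trace ~ isosbestic_trace))
    isosbestic_trace <- b[1] + b[2] * isosbestic_trace
  }
  signal_trace - isosbestic_trace
}

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift so that event timing and
#' time-of-peak measures are preserved. DC gain is 1.
#'
#' @param trace numeric vector.
#' @param sampling_rate Hz.
#' @param cutoff_hz cutoff frequency (default 0.3 Hz).
#' @return filtered numeric vector.
#' @export
lowpass <- function(trace, sampling_rate, cutoff_hz = 0.3) {
  nyq <- sampling_rate / 2
  if (cutoff_hz >= nyq)
    stop_fc(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                    cutoff_hz, nyq))
  if (cutoff_hz <= 0) stop_fc("cutoff must be > 0")
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  # mean removal plus odd-reflection padding suppresses the start-up
  # transients of the forward-backward pass (restored afterwards), so DC
  # gain is exactly 1 and edges are usable
  n <- length(trace)
  m <- mean(trace)
  x <- trace - m
  pad <- min(n - 1L, as.integer(ceiling(6 * sampling_rate / cutoff_hz)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[pad + seq_len(n)] + m
}

#' z-score a trace against basal statistics
#'
#' Computes `z = (F - F0) / sigma_F`, where `F0` and `sigma_F` are the mean
#' and standard deviation of the basal signal. By default both are taken from
#' `trace` itself restricted to `basal_window`; the pipeline instead passes
#' `stats_trace = ` the motion-corrected trace so that the scale is set before
#' low-pass filtering (see [preprocess_recording()]).
#'
#' @param trace numeric vector to be standardized (typically the filtered,
#'   corrected trace).
#' @param time time axis in seconds.
#' @param basal_window `c(start_s, end_s)` defining the basal signal;
#'   `NULL` uses the whole session.
#' @param stats_trace optional trace from which `F0`/`sigma_F` are computed
#'   (same length as `trace`); defaults to `trace`.
#' @param sensor_id label stored in the result.
#' @param provenance optional list recorded alongside (polynomial order,
#'   cutoff, ...).
#' @return an `fp_ztrace`: list with `time`, `z`, `sensor_id`, `basal_stats`
#'   (`f0`, `sigma_f`, `window`), `sampling_rate`, `provenance`.
#' @export
zscore_trace <- function(trace, time, basal_window = NULL, stats_trace = NULL,
                         sensor_id = "sensor", provenance = list()) {
  stats_trace <- stats_trace %||% trace
  if (length(stats_trace) != length(trace))
    stop_fc("`stats_trace` must have the same length as `trace`")
  if (is.null(basal_window)) basal_window <- range(time)
  in_win <- time >= basal_window[1] & time <= basal_window[2]
  if (sum(in_win) < 2L)
    stop_fc(sprintf("basal window [%g, %g] s contains fewer than 2 samples",
                    basal_window[1], basal_window[2]))
  f0 <- mean(stats_trace[in_win])
  sigma_f <- stats::sd(stats_trace[in_win])
  if (!is.finite(sigma_f) || sigma_f <= 0)
    stop_fc(sprintf("basal signal in window [%g, %g] s has zero variance",
                    basal_window[1], basal_window[2]))
  structure(list(
    time = time,
    z = (trace - f0) / sigma_f,
    sensor_id = sensor_id,
    basal_stats = list(f0 = f0, sigma_f = sigma_f, window = basal_window),
    sampling_rate = 1 / (time[2] - time[1]),
    provenance = provenance
  ), class = "fp_ztrace")
}

#' @export
print.fp_ztrace <- function(x, ...) {
  cat(sprintf("<fp_ztrace> sensor %s: %d samples @ %g Hz, F0 = %.4g, sigma_F = %.4g\n",
              x$sensor_id, length(x$z), x$sampling_rate,
              x$basal_stats$f0, x$basal_stats$sigma_f))
  invisible(x)
}

#' Full preprocessing chain for one sensor
#'
#' Fixed stage order: polynomial detrend of the sensor and its isosbestic
#' partner (each fitted individually), isosbestic subtraction, zero-phase
#' low-pass, z-scoring. Basal statistics (`F0`, `sigma_F`) are computed on the
#' motion-corrected trace over `basal_window` (whole session by default) and
#' applied to the filtered trace, so the z-unit reflects the basal variability
#' of the corrected signal. Every stage is pure: the same recording and
#' configuration always produce the same trace.
#'
#' @param rec an `fp_recording`.
#' @param sensor `"fast"` or `"slow"`.
#' @param polynomial_order detrend order (default 2).
#' @param cutoff_hz low-pass cutoff (default 0.3).
#' @param basal_window `c(start_s, end_s)` or `NULL` for the whole session.
#' @param rescale_isosbestic see [motion_correct()].
#' @param decimate_to optional target rate (Hz): recordings sampled faster are
#'   decimated (anti-aliased) before any processing. Off by default because
#'   decimation narrows the pre-filter basal bandwidth and therefore changes
#'   the z-unit scale.
#' @return an `fp_ztrace`.
#' @export
preprocess_recording <- function(rec, sensor = c("fast", "slow"),
                                 polynomial_order = 2, cutoff_hz = 0.3,
                                 basal_window = NULL,
                                 rescale_isosbestic = FALSE,
                                 decimate_to = NULL) {
  stopifnot(inherits(rec, "fp_recording"))
  sensor <- match.arg(sensor)
  roles <- rec$roles
  sig_ch <- roles$channel[roles$role == "signal" & roles$sensor == sensor]
  if (length(sig_ch) != 1L)
    stop_fc(sprintf("recording does not contain exactly one '%s' signal channel", sensor))
  iso_ch <- roles$partner[roles$channel == sig_ch]

  time <- rec$data$time_s
  sig <- rec$data[[sig_ch]]
  iso <- rec$data[[iso_ch]]
  fs <- rec$sampling_rate

  if (!is.null(decimate_to) && fs > decimate_to) {
    q <- as.integer(round(fs / decimate_to))
    sig <- as.numeric(signal::decimate(sig, q))
    iso <- as.numeric(signal::decimate(iso, q))
    time <- time[seq(1L, length(rec$data$time_s), by = q)][seq_along(sig)]
    fs <- fs / q
  }

  sig_d <- detrend_baseline(sig, polynomial_order, time)$detrended
  iso_d <- detrend_baseline(iso, polynomial_order, time)$detrended
  corrected <- motion_correct(sig_d, iso_d, rescale = rescale_isosbestic)
  filtered <- lowpass(corrected, fs, cutoff_hz)
  zscore_trace(filtered, time,
               basal_window = basal_window,
               stats_trace = corrected,
               sensor_id = sensor,
               provenance = list(polynomial_order = polynomial_order,
                                 cutoff_hz = cutoff_hz,
                                 rescale_isosbestic = rescale_isosbestic,
                                 basal_window = basal_window %||% "session"))
}

#' Preprocess both sensors of a recording
#'
#' @inheritParams preprocess_recording
#' @param ... passed to [preprocess_recording()].
#' @return named list of `fp_ztrace` (`fast`, `slow`).
#' @export
preprocess_session <- function(rec, ...) {
  list(fast = preprocess_recording(rec, "fast", ...),
       slow = preprocess_recording(rec, "slow", ...))
}

#' Write a z-scored trace with its provenance sidecar
#'
#' @param ztrace an `fp_ztrace`.
#' @param path CSV path (`time_s`, `z`); a YAML sidecar `<path>.meta.yaml`
#'   records the sensor, basal statistics and processing parameters.
#' @export
write_ztrace <- function(ztrace, path) {
  stopifnot(inherits(ztrace, "fp_ztrace"))
  readr::write_csv(tibble::tibble(time_s = ztrace$time, z = ztrace$z), path)
  meta <- c(list(sensor_id = ztrace$sensor_id,
                 f0 = ztrace$basal_stats$f0,
                 sigma_f = ztrace$basal_stats$sigma_f,
                 basal_window = ztrace$basal_stats$window,
                 version = as.character(utils::packageVersion("fibercouple"))),
            ztrace$provenance)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
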