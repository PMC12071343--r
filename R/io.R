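#' Construct a validated raw photometry recording
#'
#' Container for a multichannel fluorescence time series. Two sensor channels
#' ("fast" green and "slow" red indicator) each carry an isosbestic partner
#' channel recorded at the calcium-insensitive excitation wavelength; the
#' partner captures motion and bleaching artifacts and is subtracted during
#' preprocessing.
#'
#' @param data data frame with a `time_s` column (seconds, uniform, starting
#'   near 0) and one column per channel.
#' @param sampling_rate Hz; if `NULL`, inferred from `time_s`.
#' @param roles data frame mapping `channel` to `role`
#'   (`"signal"`/`"isosbestic"`), `sensor` (`"fast"`/`"slow"`), and for signal
#'   channels the isosbestic `partner` column name. Defaults to the standard
#'   layout `sig_fast`/`iso_fast`/`sig_slow`/`iso_slow`.
#' @param subject_id,sex subject metadata.
#' @return an object of class `fp_recording`.
#' @export
raw_recording <- function(data, sampling_rate = NULL, roles = NULL,
                          subject_id = "unknown", sex = NA_character_) {
  data <- tibble::as_tibble(data)
  if (!"time_s" %in% names(data)) stop_fc("`data` must contain a `time_s` column")
  time <- data$time_s
  if (length(time) < 2L) stop_fc("recording must contain at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop_fc("column `time_s` must be strictly increasing")
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
    stop_fc("column `time_s` is not uniform (relative jitter exceeds 1e-6)")
  sampling_rate <- sampling_rate %||% (1 / mean(dt))
  if (abs(sampling_rate * mean(dt) - 1) > 1e-6)
    stop_fc(sprintf("stated sampling rate (%g Hz) disagrees with the time base", sampling_rate))

  roles <- roles %||% default_roles()
  roles <- tibble::as_tibble(roles)
  missing_ch <- setdiff(roles$channel, names(data))
  if (length(missing_ch) > 0)
    stop_fc(sprintf("channel column(s) missing from data: %s",
                    paste(missing_ch, collapse = ", ")))
  sig <- roles[roles$role == "signal", , drop = FALSE]
  bad <- sig$channel[!(sig$partner %in% roles$channel[roles$role == "isosbestic"])]
  if (length(bad) > 0)
    stop_fc(sprintf("unpaired channel: signal channel(s) without an isosbestic partner: %s",
                    paste(bad, collapse = ", ")))
  for (ch in roles$channel) {
    v <- data[[ch]]
    if (!is.numeric(v)) stop_fc(sprintf("channel column `%s` is not numeric", ch))
    if (anyNA(v)) stop_fc(sprintf("channel column `%s` contains missing values", ch))
  }
  structure(list(data = data, sampling_rate = sampling_rate, roles = roles,
                 subject = list(id = subject_id, sex = sex)),
            class = "fp_recording")
}

default_roles <- function() {
  tibble::tibble(
    channel = c("sig_fast", "iso_fast", "sig_slow", "iso_slow"),
    role    = c("signal", "isosbestic", "signal", "isosbestic"),
    sensor  = c("fast", "fast", "slow", "slow"),
    partner = c("iso_fast", NA, "iso_slow", NA)
  )
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> subject %s: %d samples @ %g Hz, channels: %s\n",
              x$subject$id, nrow(x$data), x$sampling_rate,
              paste(x$roles$channel, collapse = ", ")))
  invisible(x)
}

#' Write / read a recording as CSV
#'
#' The on-disk dialect is a plain comma-separated file with a header row:
#' `time_s` in seconds plus one column per channel, UTF-8, full double
#' precision. Validation on read is strict: a non-uniform time base, missing
#' channel columns, an unpaired signal channel, or runs of missing values
#' longer than `max_nan_run_s` are errors naming the offending column -
#' readers reject rather than silently repair. Missing-value runs no longer
#' than `max_nan_run_s` are linearly interpolated with a message.
#'
#' @param rec an `fp_recording`.
#' @param path file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  readr::write_csv(rec$data, path)
  invisible(path)
}

#' @rdname write_recording
#' @param config optional list: `roles` (see [raw_recording()]),
#'   `subject_id`, `sex`, `sampling_rate`, `max_nan_run_s` (default 0:
#'   any missing value is an error).
#' @export
read_recording <- function(path, config = list()) {
  if (!file.exists(path)) stop_fc(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  roles <- config$roles %||% default_roles()
  max_gap <- config$max_nan_run_s %||% 0
  if (!"time_s" %in% names(data)) stop_fc("`time_s` column missing from recording CSV")
  dt <- stats::median(diff(data$time_s))
  for (ch in intersect(roles$channel, names(data))) {
    v <- data[[ch]]
    if (anyNA(v)) {
      r <- rle(is.na(v))
      run_s <- max(r$lengths[r$values]) * dt
      if (run_s > max_gap)
        stop_fc(sprintf("channel `%s`: missing-value run of %.3f s exceeds max_nan_run_s = %.3f s",
                        ch, run_s, max_gap))
      rlang::inform(sprintf("channel `%s`: interpolating %d missing sample(s)", ch, sum(is.na(v))))
      data[[ch]] <- stats::approx(data$time_s[!is.na(v)], v[!is.na(v)],
                                  xout = data$time_s, rule = 2)$y
    }
  }
  raw_recording(data,
                sampling_rate = config$sampling_rate,
                roles = roles,
                subject_id = config$subject_id %||% "unknown",
                sex = config$sex %||% NA_character_)
}

#' Construct a validated behavioral event table
#'
#' Scored behavioral events in the style of a BORIS export: one row per event
#' with absolute session times in seconds (0 = first sample; intervals are
#' half-open `[start, stop)`). Known event types are `sniff`, `loom_stimulus`,
#' `run`, and `freeze`.
#'
#' @param data data frame with columns `subject_id`, `event_type`, `start_s`,
#'   `stop_s`; optional label columns `sex`, `familiarity`
#'   (`familiar`/`unfamiliar`/`n/a`), `response_category`
#'   (`run`/`freeze`/`none`/`n/a`), `latency_s`.
#' @return a tibble of class `fp_events`.
#' @export
event_table <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("subject_id", "event_type", "start_s", "stop_s")
  missing_col <- setdiff(required, names(data))
  if (length(missing_col) > 0)
    stop_fc(sprintf("event table is missing column(s): %s",
                    paste(missing_col, collapse = ", ")))
  known <- c("sniff", "loom_stimulus", "run", "freeze")
  bad_type <- setdiff(unique(data$event_type), known)
  if (length(bad_type) > 0)
    stop_fc(sprintf("unknown event_type value(s): %s", paste(bad_type, collapse = ", ")))
  bad_rows <- which(data$stop_s < data$start_s)
  if (length(bad_rows) > 0)
    stop_fc(sprintf("stop_s < start_s in row(s): %s", paste(bad_rows, collapse = ", ")))
  for (col in c("sex", "familiarity", "response_category"))
    if (!col %in% names(data)) data[[col]] <- "n/a"
  if (!"latency_s" %in% names(data)) data$latency_s <- NA_real_
  class(data) <- c("fp_events", class(data))
  data
}

#' Write / read an event table as CSV
#' @param events an `fp_events` table.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "fp_events"))
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_fc(sprintf("file not found: %s", path))
  event_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read / write a key-value configuration file
#'
#' Configuration is a flat YAML mapping (keys such as `polynomial_order`,
#' `filter_cutoff_hz`, `basal_window`, `decimate_to`, `max_nan_run_s`).
#' @param path file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_fc(sprintf("file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config a named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
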