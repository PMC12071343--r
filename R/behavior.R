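#' Summarize social sniff bouts
#'
#' Per subject and condition (sex by familiarity): total sniff time, bout
#' count, and mean bout length. Apply the bout-length QC (>= 1 s) upstream if
#' the summary should reflect the analyzed bouts. Subjects without bouts get
#' a zero total/count and a missing mean.
#'
#' @param events an `fp_events` table (only `sniff` rows are used).
#' @param min_bout_s optional minimum bout duration applied before
#'   summarizing (default `NULL`: take bouts as scored).
#' @return tibble: `subject_id`, `sex`, `familiarity`, `total_sniff_s`,
#'   `n_bouts`, `mean_bout_s`, plus a `bouts` list-column with the individual
#'   bout durations (the per-bout unit used for bout-length comparisons).
#' @export
summarize_sniffs <- function(events, min_bout_s = NULL) {
  sn <- events[events$event_type == "sniff", , drop = FALSE]
  if (!is.null(min_bout_s))
    sn <- sn[sn$stop_s - sn$start_s >= min_bout_s, , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sn), .data$subject_id, .data$sex, .data$familiarity),
    total_sniff_s = sum(.data$stop_s - .data$start_s),
    n_bouts = dplyr::n(),
    mean_bout_s = mean(.data$stop_s - .data$start_s),
    bouts = list(.data$stop_s - .data$start_s),
    .groups = "drop"
  )
}

#' Classify behavioral responses to looming stimuli
#'
#' A trial's category is decided by the first scored `run` or `freeze` whose
#' onset falls within `[0, 8)` s of stimulus (disc) onset - responses during
#' the 8 s shadow presentation count as stimulus-elicited; later behavior
#' does not. When both behaviors occur within the window the earlier onset
#' wins. Latency is measured from disc appearance. The freeze duration
#' attributed to a stimulus is the total scored freeze time of bouts starting
#' within its window (bouts may outlast the stimulus).
#'
#' @param events an `fp_events` table containing scored `run` / `freeze`
#'   rows.
#' @param stimulus_onsets numeric vector of stimulus onset times (s), or
#'   `NULL` to take them from the table's `loom_stimulus` rows.
#' @return tibble of class `fp_looming_responses`: `trial_id`, `subject_id`,
#'   `sex`, `category` (`run`/`freeze`/`none`), `latency_s`,
#'   `freeze_duration_s`.
#' @export
classify_looming <- function(events, stimulus_onsets = NULL) {
  stim <- events[events$event_type == "loom_stimulus", , drop = FALSE]
  if (is.null(stimulus_onsets)) {
    stimulus_onsets <- stim$start_s
  }
  stimulus_onsets <- sort(stimulus_onsets)
  if (length(stimulus_onsets) >= 2 && any(diff(stimulus_onsets) < 8))
    stop_fc("stimuli closer than 8 s apart: responses cannot be attributed")
  resp <- events[events$event_type %in% c("run", "freeze"), , drop = FALSE]
  resp <- resp[order(resp$start_s), , drop = FALSE]

  rows <- lapply(seq_along(stimulus_onsets), function(i) {
    t0 <- stimulus_onsets[i]
    inwin <- resp[resp$start_s >= t0 & resp$start_s < t0 + 8, , drop = FALSE]
    meta <- stim[which.min(abs(stim$start_s - t0)), , drop = FALSE]
    subj <- if (nrow(meta)) meta$subject_id[1] else unique(events$subject_id)[1]
    sex <- if (nrow(meta)) meta$sex[1] else NA_character_
    if (nrow(inwin) == 0) {
      cat_ <- "none"; lat <- NA_real_; frz <- NA_real_
    } else {
      first <- inwin[1, ]
      cat_ <- first$event_type
      lat <- first$start_s - t0
      frz <- if (any(inwin$event_type == "freeze")) {
        fz <- inwin[inwin$event_type == "freeze", , drop = FALSE]
        sum(fz$stop_s - fz$start_s)
      } else NA_real_
      if (cat_ == "run") frz <- NA_real_
    }
    tibble::tibble(trial_id = i, subject_id = subj, sex = sex,
                   category = cat_, latency_s = lat, freeze_duration_s = frz)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fp_looming_responses", class(out))
  out
}

#' Response-category proportions by sex
#'
#' Percentage of looming trials ending in each response category, computed
#' per sex, together with the sex-by-category count table that feeds the
#' chi-square test of independence.
#'
#' @param responses an `fp_looming_responses` table (or any data frame with
#'   `sex` and `category` columns), or a named count matrix with categories
#'   in columns.
#' @return list with `proportions` (tibble: `sex`, `category`, `n`,
#'   `percent`) and `counts` (sex x category integer matrix, categories
#'   ordered run/freeze/none).
#' @export
response_proportions <- function(responses) {
  cats <- c("run", "freeze", "none")
  if (is.matrix(responses)) {
    counts <- responses[, cats, drop = FALSE]
  } else {
    if (nrow(responses) == 0) stop_fc("no responses to summarize")
    counts <- table(factor(responses$sex), factor(responses$category, levels = cats))
    counts <- unclass(as.matrix(counts))
  }
  prop <- do.call(rbind, lapply(rownames(counts), function(s) {
    n <- counts[s, ]
    tibble::tibble(sex = s, category = cats, n = as.integer(n),
                   percent = 100 * as.numeric(n) / sum(n))
  }))
  list(proportions = tibble::as_tibble(prop), counts = counts)
}
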