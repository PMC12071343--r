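# shared fixture builders; everything is generated in code

# a ztrace with prescribed z values (bypasses standardization)
make_ztrace <- function(z, fs = 100, sensor = "slow", t0 = 1 / fs) {
  time <- t0 + (seq_along(z) - 1) / fs
  structure(list(time = time, z = z, sensor_id = sensor,
                 basal_stats = list(f0 = 0, sigma_f = 1, window = range(time)),
                 sampling_rate = fs, provenance = list()),
            class = "fp_ztrace")
}

# sniff event rows at given onsets
sniff_events <- function(onsets, durations = 2, subject = "m1",
                         familiarity = "familiar", sex = "female") {
  event_table(tibble::tibble(
    subject_id = subject, event_type = "sniff",
    start_s = onsets, stop_s = onsets + durations,
    sex = sex, familiarity = familiarity
  ))
}

# a single-trial fp_trials table with prescribed dz, for metric/coupling tests
make_trials <- function(dz_list, rel_time, paradigm = "social",
                        subject = "m1", sensor = "slow") {
  spec <- alignment_spec(paradigm,
                         extract_window = range(rel_time),
                         baseline_window = if (paradigm == "social")
                           c(rel_time[1], -3) else c(rel_time[1], 0))
  base_idx <- which(rel_time >= spec$baseline_window[1] &
                    rel_time <= spec$baseline_window[2])
  out <- dplyr::bind_rows(lapply(seq_along(dz_list), function(i) {
    tibble::tibble(subject_id = subject, sensor_id = sensor, trial_idx = i,
                   event_type = if (paradigm == "social") "sniff" else "loom_stimulus",
                   start_s = 100 * i, stop_s = 100 * i + 2, bout_s = 2,
                   sex = "female", familiarity = "familiar",
                   response_category = "n/a",
                   rel_time = list(rel_time), dz = list(dz_list[[i]]),
                   qc_status = "included")
  }))
  attr(out, "spec") <- spec
  attr(out, "baseline_idx") <- base_idx
  class(out) <- c("fp_trials", class(out))
  out
}

# independent brute-force peak scan (mirrors the documented rule, coded flat)
oracle_peak <- function(rel_time, dz, curve, ignore_fraction) {
  if (curve$status != "ok") return(NULL)
  idx <- curve$idx
  pol <- curve$sign
  rng <- max(dz) - min(dz)
  best_val <- -Inf; best_i <- NA
  for (j in seq_along(idx)) {
    i <- idx[j]
    yl <- if (j == 1) -Inf else dz[idx[j - 1]] * pol
    yr <- if (j == length(idx)) -Inf else dz[idx[j + 1]] * pol
    y <- dz[i] * pol
    if (y >= yl && y >= yr) {
      h <- if (pol > 0) dz[i] - min(dz) else max(dz) - dz[i]
      if (h >= ignore_fraction * rng && y > best_val) {
        best_val <- y; best_i <- i
      }
    }
  }
  if (!is.finite(best_val)) return(NULL)
  list(peak_dz = dz[best_i], t_peak = rel_time[best_i])
}
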