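# independent region enumeration used to cross-check curve selection
oracle_regions <- function(dz) {
  s <- sign(dz)
  starts <- c(); ends <- c(); i <- 1
  while (i <= length(s)) {
    if (s[i] != 0) {
      j <- i
      while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1
    } else i <- i + 1
  }
  list(starts = starts, ends = ends)
}

test_that("curve selection picks the zero-bounded region per paradigm", {
  rt <- seq(-8, 5, by = 0.01)
  hump <- ifelse(rt > -1 & rt < 3, sin(pi * (rt + 1) / 4), 0)
  cv <- select_curve(rt, hump, "social")
  expect_equal(cv$status, "ok")
  expect_equal(cv$start_s, -1 + 0.01, tolerance = 0.02)
  expect_equal(cv$end_s, 3 - 0.01, tolerance = 0.02)

  rtl <- seq(-5, 15, by = 0.01)
  two <- ifelse(rtl > 0 & rtl < 2, sin(pi * rtl / 2),
         ifelse(rtl > 5.5 & rtl < 7.5, 0.5 * sin(pi * (rtl - 5.5) / 2), 0))
  cvl <- select_curve(rtl, two, "looming")
  expect_gt(cvl$start_s, 5)   # the second hump overlaps 5-8 s
  expect_lt(cvl$end_s, 8)

  expect_equal(select_curve(rt, numeric(length(rt)), "social")$status, "no_curve")
})

test_that("overlap ties go to the earlier region (verified by enumeration)", {
  rtl <- seq(-5, 15, by = 0.01)
  # two positive humps each overlapping [5, 8] by exactly 1 s
  dz <- ifelse(rtl > 4.5 & rtl < 6, 0.3,
        ifelse(rtl > 7 & rtl < 8.5, 0.4, 0))
  cv <- select_curve(rtl, dz, "looming")
  reg <- oracle_regions(dz)
  ov <- pmin(rtl[reg$ends], 8) - pmax(rtl[reg$starts], 5)
  expect_equal(which.max(ov), 1L)   # enumeration confirms a tie broken early
  expect_lt(cv$start_s, 5)
  expect_lt(cv$end_s, 7)
})

test_that("peak detection finds apexes and honors the ignore rule", {
  rt <- seq(-8, 5, by = 0.01)
  tri <- pmax(0, 0.4 * (1 - abs(rt - 1)))
  cv <- select_curve(rt, tri, "social")
  pk <- detect_peak(rt, tri, cv, 0.05)
  expect_equal(pk$peak_dz, 0.4)
  expect_equal(pk$t_peak, 1.0)

  # trial range [0, 1]: a secondary 0.04 blip is below the 5% floor
  blip_only <- pmax(0, 0.04 * (1 - abs(rt + 4) * 10))
  full <- blip_only + pmax(0, 1 - abs(rt - 1) * 4)
  cv_blip <- list(status = "ok", idx = which(blip_only > 0), sign = 1,
                  start_s = NA, end_s = NA)
  expect_null(detect_peak(rt, full, cv_blip, 0.05))
})

test_that("peak detection matches the exhaustive scan on random trials", {
  set.seed(99)
  for (i in 1:200) {
    rt <- seq(-8, 5, by = 0.05)
    dz <- cumsum(rnorm(length(rt), sd = 0.05))   # random walk
    dz <- dz - mean(dz[rt <= -3])
    frac <- sample(c(0.05, 0.10), 1)
    cv <- select_curve(rt, dz, "social")
    if (cv$status != "ok") next
    got <- detect_peak(rt, dz, cv, frac)
    want <- oracle_peak(rt, dz, cv, frac)
    expect_identical(got, want)
  }
})

test_that("AUC is trapezoidal, signed, and matches closed forms", {
  rt <- seq(-2, 4, by = 0.01)
  tri <- pmax(0, 1 - abs(rt))   # height 1, base 2
  cv <- select_curve(rt, tri, "social")
  expect_equal(compute_auc(rt, tri, cv), 1.0, tolerance = 1e-3)

  # half-sine amplitude A over duration T: area 2AT/pi
  A <- 0.7; T <- 3
  hs <- ifelse(rt >= 0 & rt <= T, A * sin(pi * rt / T), 0)
  cvh <- select_curve(rt, hs, "social")
  expect_equal(compute_auc(rt, hs, cvh), 2 * A * T / pi, tolerance = 1e-3 * 2 * A * T / pi)

  neg <- -tri
  cvn <- select_curve(rt, neg, "social")
  expect_equal(compute_auc(rt, neg, cvn), -compute_auc(rt, tri, cv))
})

test_that("AUC is additive over splits and linear in scaling", {
  rt <- seq(0, 2, by = 0.01)
  dz <- sin(pi * rt / 2)^2 + 0.1
  idx <- seq_along(rt)
  cut <- 101
  full <- pracma::trapz(rt, dz)
  expect_equal(pracma::trapz(rt[1:cut], dz[1:cut]) +
               pracma::trapz(rt[cut:length(rt)], dz[cut:length(rt)]), full)
  cv <- list(status = "ok", idx = idx, sign = 1, start_s = 0, end_s = 2)
  expect_equal(compute_auc(rt, 3 * dz, cv), 3 * compute_auc(rt, dz, cv))
})

test_that("epoch means use closed [5,8], strictly-after-8, and the baseline window", {
  rt <- seq(-5, 15, by = 0.01)
  expect_equal(epoch_means(rt, rep(0.25, length(rt))),
               list(baseline = 0.25, loom = 0.25, post = 0.25))

  step <- ifelse(rt >= 5, 0.3, 0)
  em <- epoch_means(rt, step)
  expect_equal(em$loom, 0.3)
  expect_equal(em$baseline, 0)
  expect_equal(em$post, 0.3)

  # strictly after 8: a spike exactly at 8 s belongs to the loom epoch only
  spike <- as.numeric(abs(rt - 8) < 1e-9)
  em2 <- epoch_means(rt, spike)
  expect_gt(em2$loom, 0)
  expect_equal(em2$post, 0)

  expect_error(epoch_means(seq(-5, 10, by = 0.01), rep(0, 1501)), "post")
})

test_that("epoch means agree with an independent windowed average to 1e-12", {
  truth <- simulation_truth("looming", duration = 600, n_events = 6, seed = 21)
  s <- generate_looming_session(truth)
  z <- preprocess_recording(s$recording, "slow")
  tr <- apply_qc(extract_trials(z, s$events, alignment_spec("looming")))
  mets <- trial_metrics(tr)
  inc <- included_trials(tr)
  for (i in seq_len(nrow(inc))) {
    rt <- inc$rel_time[[i]]; dz <- inc$dz[[i]]
    expect_equal(mets$mean_5_8[i], sum(dz[rt >= 5 & rt <= 8]) / sum(rt >= 5 & rt <= 8),
                 tolerance = 1e-12)
    expect_equal(mets$mean_post[i], sum(dz[rt > 8 & rt <= 15]) / sum(rt > 8 & rt <= 15),
                 tolerance = 1e-12)
  }
})
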