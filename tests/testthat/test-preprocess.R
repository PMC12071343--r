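test_that("polynomial detrending removes curves of matching order exactly", {
  t <- seq(0, 100, by = 0.01)
  quad <- 3 + 0.5 * t - 0.02 * t^2
  expect_lt(max(abs(detrend_baseline(quad, 2, t)$detrended)), 1e-8)
  expect_lt(max(abs(detrend_baseline(rep(4.2, 500), 5)$detrended)), 1e-10)
  expect_error(detrend_baseline(1:10, -1), "order")
  expect_error(detrend_baseline(1:3, 5), "length")
})

test_that("order-4 detrend captures a double-exponential bleach to <5% RMS", {
  t <- seq(0.01, 600, by = 0.01)
  bleach <- 10 * exp(-t / 300) + 5 * exp(-t / 1200)
  res <- detrend_baseline(bleach, 4, t)$detrended
  amp <- diff(range(bleach))
  expect_lt(sqrt(mean(res^2)), 0.05 * amp)
  # independent normal-equation oracle on the scaled time base
  ts <- (t - mean(t)) / sd(t)
  X <- outer(ts, 0:4, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% bleach)
  res_oracle <- bleach - as.numeric(X %*% beta)
  expect_equal(sqrt(mean(res^2)), sqrt(mean(res_oracle^2)), tolerance = 1e-6)
})

test_that("isosbestic subtraction behaves as stated", {
  x <- sin(seq(0, 10, by = 0.01))
  expect_equal(motion_correct(x, numeric(length(x))), x)
  expect_equal(motion_correct(x, x), numeric(length(x)))
  expect_error(motion_correct(x, x[-1]), "length")

  # shared artifact at 5x the noise amplitude is cancelled
  set.seed(42)
  n <- 20000
  artifact <- numeric(n)
  artifact[2000:2200] <- 5 * sin(seq(0, pi, length.out = 201))
  sig <- artifact + rnorm(n)
  iso <- artifact + rnorm(n)
  corrected <- motion_correct(sig, iso)
  expect_lt(abs(cor(corrected, artifact)), 0.1)
})

test_that("the low-pass filter has unit DC gain, strong stopband rejection and zero phase", {
  expect_lt(max(abs(lowpass(rep(2.5, 1000), 100) - 2.5)), 1e-9)

  t <- seq(0, 120, by = 0.01)
  sine <- sin(2 * pi * 5 * t)
  out <- lowpass(sine, 100)
  core <- seq(2000, length(t) - 2000)  # avoid filter edge transients
  rms_ratio <- sqrt(mean(out[core]^2)) / sqrt(mean(sine[core]^2))
  expect_lt(rms_ratio, 0.01)
  # analytic magnitude of the forward-backward 2nd-order Butterworth
  gain <- 1 / (1 + (5 / 0.3)^4)
  expect_lt(rms_ratio, 10 * gain)

  pulse <- exp(-((t - 60)^2) / (2 * 4))
  out_p <- lowpass(pulse, 100)
  expect_equal(which.max(out_p), which.max(pulse))

  expect_error(lowpass(sine, 100, cutoff_hz = 60), "Nyquist")
})

test_that("z-scoring applies (F - F0) / sigma_F with basal-window statistics", {
  trace <- c(1, 2, 3, 3)   # basal window = first three samples: mean 2, sd 1
  zt <- zscore_trace(trace, time = 1:4, basal_window = c(1, 3))
  expect_equal(zt$z[4], 1.0)
  expect_equal(zt$basal_stats$f0, 2)
  expect_equal(zt$basal_stats$sigma_f, 1)

  set.seed(1)
  x <- rnorm(5000)
  zt2 <- zscore_trace(x, time = (1:5000) / 100, basal_window = c(5, 30))
  w <- zt2$time >= 5 & zt2$time <= 30
  expect_lt(abs(mean(zt2$z[w])), 1e-9)
  expect_lt(abs(sd(zt2$z[w]) - 1), 1e-9)

  expect_error(zscore_trace(rep(1, 100), (1:100) / 10), "zero variance")
})

test_that("the full chain is pure and keeps a noise-only session near zero", {
  truth <- simulation_truth("social", duration = 300, n_events = 2,
                            event_onsets = c(100, 200), event_amplitudes = c(0, 0),
                            motion = "none", seed = 9)
  s <- generate_social_session(truth)
  z1 <- preprocess_recording(s$recording, "slow")
  z2 <- preprocess_recording(s$recording, "slow")
  expect_identical(z1$z, z2$z)
  expect_gte(mean(abs(z1$z) <= 2.2), 0.95)
})

test_that("a noiseless no-event session leaves no corrected signal", {
  # equal bleach in signal and isosbestic channel: the subtraction cancels
  # the drift exactly, whatever the detrend leaves behind
  truth <- simulation_truth("social", duration = 300, n_events = 2,
                            event_onsets = c(100, 200), event_amplitudes = c(0, 0),
                            noise_sd = 0, motion = "none",
                            bleach_channel_scale = c(sig_fast = 1, iso_fast = 1,
                                                     sig_slow = 1, iso_slow = 1),
                            seed = 2)
  s <- generate_social_session(truth)
  rec <- s$recording
  sig <- detrend_baseline(rec$data$sig_slow, 2, rec$data$time_s)$detrended
  iso <- detrend_baseline(rec$data$iso_slow, 2, rec$data$time_s)$detrended
  corrected <- motion_correct(sig, iso)
  expect_lt(max(abs(corrected)), 1e-9 * diff(range(rec$data$sig_slow)))

  # with channel-specific bleach amplitudes, only the detrending tolerance
  # remains: residual below 1e-4 of the session's fluorescence range
  truth2 <- simulation_truth("social", duration = 300, n_events = 2,
                             event_onsets = c(100, 200), event_amplitudes = c(0, 0),
                             noise_sd = 0, motion = "none", seed = 2)
  rec2 <- generate_social_session(truth2)$recording
  sig2 <- detrend_baseline(rec2$data$sig_slow, 4, rec2$data$time_s)$detrended
  iso2 <- detrend_baseline(rec2$data$iso_slow, 4, rec2$data$time_s)$detrended
  expect_lt(max(abs(motion_correct(sig2, iso2))),
            1e-4 * diff(range(rec2$data$sig_slow)))
})
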