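test_that("wide-band downsampling preserves the passband and kills aliases", {
  cc <- downsample_wideband(rep(3.3, 32000), 32000, 1250)
  inner <- cc$samples[100:(length(cc$samples) - 100)]
  expect_lt(diff(range(inner)), 1e-6)            # constant stays constant
  expect_equal(mean(inner), 3.3, tolerance = 0.01)

  t <- (0:(32000 * 2 - 1)) / 32000
  d <- downsample_wideband(sin(2 * pi * 100 * t), 32000, 1250)
  expect_equal(d$fs_hz, 1250)
  expect_equal(max(abs(d$samples[500:2000])), 1, tolerance = 0.01)

  d5 <- downsample_wideband(sin(2 * pi * 5000 * t), 32000, 1250)
  expect_lt(20 * log10(max(abs(d5$samples[500:2000]))), -40)

  expect_error(downsample_wideband(rnorm(100), 500, 1250), "fs_in")
})

test_that("band envelope approximates the rectified-sine mean in band", {
  n <- 1250 * 20
  lfp <- lfp_signal(10 * sin(2 * pi * 45 * (0:(n - 1)) / 1250), 1250)
  env <- band_envelope(lfp, c(30, 60))
  inner <- env$envelope[2000:(n - 2000)]
  expect_true(all(env$envelope >= 0))
  expect_equal(mean(inner), 10 * 2 / pi, tolerance = 0.02)

  out <- band_envelope(lfp_signal(10 * sin(2 * pi * 150 * (0:(n - 1)) / 1250), 1250),
                       c(30, 60))
  expect_lt(mean(out$envelope[2000:(n - 2000)]), 0.1)

  expect_error(band_envelope(lfp, c(30, 700)), "fs/2")
  expect_error(band_envelope(lfp_signal(rep(0, 5000), 1250), c(30, 60)),
               "degenerate")
})

test_that("event detection applies the 2 SD / 25 ms / 1 SD rule", {
  # hand-built envelope object: constant at the mean -> no events
  flat <- structure(list(envelope = rep(1, 5000), mean = 1, sd = 0.2,
                         fs_hz = 1250, band_hz = c(30, 60)),
                    class = "band_envelope")
  expect_equal(nrow(detect_events(flat)$intervals), 0L)

  # a single boxcar excursion: detected, extended to the 1 SD edges
  e <- rep(1, 5000)
  e[2000:2600] <- 1.25          # above 1 SD from sample 2000
  e[2100:2500] <- 1.6           # above 2 SD for 400 samples (320 ms)
  env <- structure(list(envelope = e, mean = 1, sd = 0.2, fs_hz = 1250,
                        band_hz = c(30, 60)), class = "band_envelope")
  ev <- detect_events(env, 2, 1, 25)
  expect_equal(nrow(ev$intervals), 1L)
  expect_equal(ev$intervals[1, 1], 1999 / 1250, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ev$intervals[1, 2], 2600 / 1250, tolerance = 1e-9,
               ignore_attr = TRUE)

  # too-short excursion rejected
  e2 <- rep(1, 5000); e2[3000:3020] <- 2  # 16.8 ms
  env2 <- structure(list(envelope = e2, mean = 1, sd = 0.2, fs_hz = 1250,
                         band_hz = c(30, 60)), class = "band_envelope")
  expect_equal(nrow(detect_events(env2, 2, 1, 25)$intervals), 0L)

  # planted 5-SD 40 Hz burst in pink noise -> exactly one event covering it
  g <- generate_lfp_with_events(
    60, 1250, list(list(band_hz = c(30, 60), amplitude_sd = 5,
                        duration_ms = 100, count = 1, label = "slow")),
    seed = 7)
  env3 <- band_envelope(g$lfp, c(30, 60))
  ev3 <- detect_events(env3, 2, 1, 25, label = "slow_gamma")
  tr <- g$truth$slow$intervals[1, ]
  covering <- ev3$intervals[, 1] <= tr[1] + 0.025 & ev3$intervals[, 2] >= tr[2] - 0.025
  expect_equal(sum(covering), 1L)
})

test_that("event detection is idempotent and monotone in the threshold", {
  g <- generate_lfp_with_events(
    60, 1250, list(list(band_hz = c(30, 60), amplitude_sd = 4,
                        duration_ms = 100, count = 5, label = "slow")),
    seed = 8)
  env <- band_envelope(g$lfp, c(30, 60))
  ev1 <- detect_events(env, 2, 1, 25)
  ev2 <- detect_events(env, 2, 1, 25)
  expect_identical(ev1$intervals, ev2$intervals)

  tot <- vapply(c(3, 2.5, 2, 1.5), function(th) {
    lhensemble:::interval_total(detect_events(env, th, 1, 25)$intervals)
  }, numeric(1))
  expect_true(all(diff(tot) >= 0))  # lower threshold, never less event time
})

test_that("nonrhythmic epochs avoid oscillations and detected events", {
  # planted strong theta is excluded from nonrhythmic time
  set.seed(9)
  n <- 1250 * 60
  g <- generate_lfp_with_events(60, 1250, list(), seed = 10)
  x <- g$lfp$samples
  theta_iv <- c(20, 24)
  idx <- (theta_iv[1] * 1250 + 1):(theta_iv[2] * 1250)
  x[idx] <- x[idx] + 6 * sd(x) * sin(2 * pi * 7 * seq_along(idx) / 1250)
  lfp <- lfp_signal(x, 1250)
  nr <- detect_nonrhythmic(lfp)
  expect_true(all(diff(nr$intervals[, 1]) > 0))
  expect_true(all(nr$intervals[, 2] > nr$intervals[, 1]))
  ov_theta <- sum(lhensemble:::overlap_lengths(theta_iv + c(0.1, -0.1),
                                               nr$intervals))
  expect_equal(ov_theta, 0)

  # zero overlap with detected gamma events when they are excluded
  g2 <- generate_lfp_with_events(
    60, 1250, list(list(band_hz = c(30, 60), amplitude_sd = 5,
                        duration_ms = 100, count = 5, label = "slow")),
    seed = 11)
  env <- band_envelope(g2$lfp, c(30, 60))
  ev <- detect_events(env, 2, 1, 25)
  nr2 <- detect_nonrhythmic(g2$lfp, exclude = list(ev))
  ov <- sum(vapply(seq_len(nrow(ev$intervals)), function(i) {
    sum(lhensemble:::overlap_lengths(ev$intervals[i, ], nr2$intervals))
  }, numeric(1)))
  expect_equal(ov, 0)

  expect_error(detect_nonrhythmic(lfp, bands = list(c(500, 700))), "Nyquist")
})

test_that("multitaper PSD recovers line spectra and total power", {
  fs <- 1250
  x <- sin(2 * pi * 42 * (0:(fs * 10 - 1)) / fs)
  p <- multitaper_psd(x, fs)
  df <- p$freqs[2] - p$freqs[1]
  expect_lte(abs(p$freqs[which.max(p$power)] - 42), df)

  set.seed(14)
  w <- rnorm(1024 * 51)  # ~100 half-overlapping windows
  pw <- multitaper_psd(w, fs)
  expect_equal(sum(pw$power) * df, var(w), tolerance = 0.1)
  sel <- pw$freqs >= 5 & pw$freqs <= 200
  expect_lte(max(pw$power[sel]) / min(pw$power[sel]), 3)

  expect_error(multitaper_psd(rnorm(100), fs, window = 1024), "shorter")
})
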