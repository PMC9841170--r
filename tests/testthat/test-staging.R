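sine_epoch <- function(freq, dt = 0.005, dur = 10) {
  sin(2 * pi * freq * seq(0, dur - dt, by = dt))
}

test_that("epoch features recover spectral fractions", {
  dt <- 0.005
  emg <- rnorm(2000)
  f2 <- epoch_features(sine_epoch(2, dt), emg, dt)
  expect_gt(f2$delta_frac, 0.95)
  expect_lt(f2$theta_frac, 0.05)
  f7 <- epoch_features(sine_epoch(7, dt), emg, dt)
  expect_gt(f7$theta_frac, 0.95)
  # white noise: fractions approximate bandwidth ratios (Nyquist 100 Hz)
  set.seed(20)
  fr <- rowMeans(replicate(20, {
    f <- epoch_features(rnorm(2000), emg, dt)
    c(f$delta_frac, f$theta_frac, f$alpha_frac)
  }))
  expect_equal(fr, c(4, 5, 4) / 100, tolerance = 0.3)
  expect_error(epoch_features(sine_epoch(2, dt, dur = 5), emg, dt), "expected 10")
})

test_that("the scoring cascade follows the visual criteria", {
  th <- staging_thresholds()
  f <- function(d, t, a, emg) list(delta_frac = d, theta_frac = t,
                                   alpha_frac = a, emg_rms = emg)
  # delta-dominated, low EMG -> NREM (delta fraction > 30%)
  expect_identical(score_epoch(f(0.40, 0.05, 0.02, 0.5), 1, th), "NREM")
  # theta > 20%, low delta, low EMG -> REM
  expect_identical(score_epoch(f(0.10, 0.25, 0.02, 0.5), 1, th), "REM")
  # 8-12 Hz fraction > 10% with high EMG -> WAKE
  expect_identical(score_epoch(f(0.10, 0.10, 0.15, 2), 1, th), "WAKE")
  # nothing matches -> UNSCORED
  expect_identical(score_epoch(f(0.10, 0.10, 0.05, 2), 1, th), "UNSCORED")
})

test_that("whole-record scoring is deterministic and epoch-local", {
  pr <- quiet_profiles()
  g <- generate_recording(pr$sleep, 120, seed = 21, sampling_interval_s = test_dt)
  h1 <- score_recording(g$recording, emg_threshold = 2)
  h2 <- score_recording(g$recording, emg_threshold = 2)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 12)
  # 95-s record scores 9 epochs
  r95 <- recording(matrix(rnorm(3 * 95 / test_dt), ncol = 3), test_dt)
  expect_equal(nrow(score_recording(r95)), 9)
  r2 <- recording(matrix(rnorm(4000), ncol = 2),
                  0.01, channel_labels = c("EEG-L", "EEG-R"))
  expect_error(score_recording(r2), "no EMG")
})

test_that("raising the delta threshold never increases the NREM count", {
  pr <- quiet_profiles()
  g <- generate_recording(pr$sleep, 200, seed = 22, sampling_interval_s = test_dt)
  counts <- vapply(c(0.2, 0.3, 0.5, 0.7, 0.9), function(thr) {
    th <- staging_thresholds(); th$delta_frac <- thr
    sum(score_recording(g$recording, thresholds = th,
                        emg_threshold = 2)$raw_label == "NREM")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("scoring agrees with generator ground truth state by state", {
  pr <- quiet_profiles()
  w <- generate_recording(pr$wake, 300, seed = 23, sampling_interval_s = test_dt)
  s <- generate_recording(pr$sleep, 300, seed = 24, sampling_interval_s = test_dt)
  # cohort-level EMG threshold: between sleep and wake tone
  rms <- function(g) median(vapply(epochize(g$recording, 10, channels = "EMG"),
                                   function(e) sqrt(mean(e$samples^2)), 0))
  thr <- (rms(w) + rms(s)) / 2
  hw <- score_recording(w$recording, emg_threshold = thr)
  hs <- score_recording(s$recording, emg_threshold = thr)
  expect_gte(mean(hw$label == "WAKE"), 0.9)
  expect_gte(mean(hs$label == "NREM"), 0.9)
})
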