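test_that("generation is deterministic and cohorts are well-formed", {
  pr <- quiet_profiles()
  a <- generate_recording(pr$wake, 60, seed = 7, sampling_interval_s = test_dt)
  b <- generate_recording(pr$wake, 60, seed = 7, sampling_interval_s = test_dt)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth$bursts, b$ground_truth$bursts)

  co <- generate_cohort(pr, n_per_group = 3, length_s = 60, seed = 11,
                        sampling_interval_s = test_dt)
  expect_length(co, 9)
  expect_false(any(duplicated(names(co))))
  co2 <- generate_cohort(pr, n_per_group = 3, length_s = 60, seed = 11,
                         sampling_interval_s = test_dt)
  expect_identical(co[[5]]$recording$samples, co2[[5]]$recording$samples)
  # stage labels restricted to the hypnogram alphabet
  labs <- unlist(lapply(co, function(it) it$ground_truth$stage_labels))
  expect_true(all(labs %in% c("wake", "NREM", "REM")))
})

test_that("parameter validation rejects bad inputs", {
  pr <- quiet_profiles()
  expect_error(coherent_pair(10, test_dt, band("theta", 4, 8), 1.2, 1),
               "target_coherence")
  expect_error(coherent_pair(10, test_dt, band("hf", 100, 200), 0.5, 1),
               "Nyquist")
  expect_error(generate_recording(pr$wake, -5, 1), "length_s")
  expect_error(generate_cohort(list(), 3, 60, 1), "non-empty")
  expect_error(generate_cohort(pr, 1, 60, 1), "n_per_group")
  expect_error(state_profile("x", c(theta = -1), 0.5), "variances")
  expect_error(state_profile("x", c(bogus = 1), 0.5), "unknown component")
})

test_that("coherent_pair hits its closed-form coherence target", {
  b <- band("theta", 4, 8)
  # identical in-band component at c = 1
  r1 <- coherent_pair(300, test_dt, b, 1, seed = 2)
  co1 <- coherence(r1$samples[, 1], r1$samples[, 2], test_dt)
  expect_gt(band_coherence(co1, b), 0.99)
  # independent channels: estimator bias floor well below 0.2
  r0 <- coherent_pair(2000, test_dt, b, 0, seed = 3)
  co0 <- coherence(r0$samples[, 1], r0$samples[, 2], test_dt)
  expect_lt(band_coherence(co0, b), 0.2)
  # intermediate target recovered within +-0.05 on a long record
  r5 <- coherent_pair(4000, test_dt, b, 0.5, seed = 4)
  co5 <- coherence(r5$samples[, 1], r5$samples[, 2], test_dt)
  expect_equal(band_coherence(co5, b), 0.5, tolerance = 0.1)
  expect_lt(abs(band_coherence(co5, b) - 0.5), 0.05)
})

test_that("per-band variance of generated EEG matches the profile accounting", {
  pr <- quiet_profiles()
  g <- generate_recording(pr$sleep, 2000, seed = 5, sampling_interval_s = test_dt)
  x <- g$recording$samples[, 1]
  # oracle: rectangular band variance straight off the periodogram
  xc <- x - mean(x)
  pg <- Mod(fft(xc))^2 / length(xc)^2
  fr <- (seq_along(pg) - 1) / (length(xc) * test_dt)
  band_var <- function(lo, hi) 2 * sum(pg[fr > lo & fr <= hi])
  for (b in list(band("delta_slow", 0.1, 0.5), band("theta", 4, 8),
                 band("delta_wide", 0.5, 4))) {
    expected <- expected_band_power(pr$sleep, b, test_dt)
    expect_equal(band_var(b$f_lo, b$f_hi), expected, tolerance = 0.1)
  }
})

test_that("injected theta coherence is recovered by the coherence module", {
  pr <- quiet_profiles()
  for (st in names(pr)) {
    g <- generate_recording(pr[[st]], 2000, seed = 6, sampling_interval_s = test_dt)
    co <- coherence(g$recording$samples[, 1], g$recording$samples[, 2], test_dt)
    expect_lt(abs(band_coherence(co, "theta") - g$ground_truth$theta_coherence),
              0.05)
  }
})

test_that("injected burst durations match the profile mean at >= 200 bursts", {
  pr <- quiet_profiles()
  g <- generate_recording(pr$sleep, 2000, seed = 8, sampling_interval_s = test_dt)
  bursts <- g$ground_truth$bursts
  expect_gt(nrow(bursts), 200)
  # drop bursts clipped by the record end
  full <- bursts[bursts$end < 2000, ]
  expect_equal(mean(full$duration), pr$sleep$burst_mean_duration_s,
               tolerance = 0.1)
  # non-overlapping
  expect_true(all(diff(as.vector(t(bursts[, c("start", "end")]))) >= 0))
})
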