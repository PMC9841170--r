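test_that("the transform localises tones and scales with amplitude", {
  dt <- 0.02                                   # 50 Hz
  t <- seq(0, 120 - dt, by = dt)
  freqs <- exp(seq(log(1), log(20), length.out = 24))
  x <- sin(2 * pi * 6 * t)
  surf <- cwt(x, dt, freqs)
  inside <- surf$times > 5 & surf$times < 115  # outside the COI
  ridge <- surf$frequencies[apply(surf$power[, inside], 2, which.max)]
  expect_true(all(abs(ridge - 6) / 6 < 0.1))
  # two tones -> two persistent ridges
  x2 <- sin(2 * pi * 2 * t) + sin(2 * pi * 6 * t)
  sk2 <- skeleton(cwt(x2, dt, freqs))
  long <- Filter(function(r) nrow(r) > 0.8 * sum(inside), sk2)
  fr <- sort(vapply(long, function(r) median(r$freq_hz), numeric(1)))
  expect_length(fr, 2)
  expect_equal(fr, c(2, 6), tolerance = 0.15)
  # linearity: power of a*x is a^2 times power of x
  sa <- cwt(3 * x, dt, freqs)
  expect_equal(sa$power, 9 * surf$power, tolerance = 1e-9)
  expect_error(cwt(x, dt, numeric(0)), "empty")
  expect_error(cwt(x, dt, c(5, 30)), "Nyquist")
})

test_that("white-noise power is flat in frequency under the 1/f normalisation", {
  set.seed(40)
  dt <- 0.02
  freqs <- exp(seq(log(1), log(20), length.out = 12))
  avg <- rowMeans(sapply(1:6, function(k) {
    surf <- cwt(rnorm(12000), dt, freqs)
    rowMeans(surf$power[, surf$times > 10 & surf$times < 230])
  }))
  expect_lt(max(avg) / min(avg), 1.5)
})

test_that("skeleton of silence is empty and of a tone is one ridge", {
  dt <- 0.02
  freqs <- exp(seq(log(1), log(20), length.out = 24))
  expect_length(skeleton(cwt(rep(0, 5000), dt, freqs), floor_power = 1e-12), 0)
  t <- seq(0, 100 - dt, by = dt)
  sk <- skeleton(cwt(sin(2 * pi * 6 * t), dt, freqs))
  main <- Filter(function(r) nrow(r) > 4000, sk)
  expect_length(main, 1)
})

test_that("pattern detection recovers injected events", {
  dt <- 0.02
  t <- seq(0, 60 - dt, by = dt)
  # one 2-s theta burst in weak noise
  set.seed(41)
  x <- 0.05 * rnorm(length(t)) +
    ifelse(t >= 30 & t < 32, 1, 0) * sin(2 * pi * 6 * t)
  freqs <- exp(seq(log(2.5), log(12.4), length.out = 20))
  surf <- cwt(x, dt, freqs)
  # explicit floor between the noise and burst power levels: the default
  # median-based floor targets continuous EEG backgrounds, not near-silence
  pats <- detect_patterns(skeleton(surf), "theta", surf, power_floor = 0.2)
  expect_equal(nrow(pats$events), 1)
  expect_equal(pats$events$duration, 2, tolerance = 0.25)
  expect_equal(pats$events$peak_freq_hz, 6, tolerance = 0.5)
  # continuous tone: one event spanning (almost) the record
  xt <- sin(2 * pi * 6 * t) + 0.05 * rnorm(length(t))
  st <- cwt(xt, dt, freqs)
  pt <- detect_patterns(skeleton(st), "theta", st, power_floor = 0.3)
  expect_equal(nrow(pt$events), 1)
  expect_gt(pt$events$duration, 55)
  # sub-floor noise: no events
  sn <- cwt(0.01 * rnorm(length(t)), dt, freqs)
  pn <- detect_patterns(skeleton(sn), "theta", sn, power_floor = 1)
  expect_equal(nrow(pn$events), 0)
  expect_equal(as.numeric(mean_duration(pn)), 0)
  expect_true(attr(mean_duration(pn), "empty"))
  expect_equal(mean_duration(list(events = data.frame(duration = c(1, 2, 3)))), 2)
})

test_that("event durations never exceed the record and ignore amplitude scale", {
  pr <- quiet_profiles()
  g <- generate_recording(pr$wake, 200, seed = 42, sampling_interval_s = test_dt)
  x <- g$recording$samples[, 1]
  p1 <- band_patterns(x, test_dt, "theta")
  expect_lte(sum(p1$events$duration), 200)
  p2 <- band_patterns(5 * x, test_dt, "theta")
  expect_equal(p2$events$duration, p1$events$duration, tolerance = 1e-9)
})

test_that("mean burst duration is recovered within 10% at >= 200 bursts", {
  pr <- quiet_profiles()
  g <- generate_recording(pr$sleep, 2800, seed = 43, sampling_interval_s = test_dt)
  expect_gte(nrow(g$ground_truth$bursts), 200)
  pats <- band_patterns(g$recording$samples[, 1], test_dt, "theta")
  expect_equal(as.numeric(mean_duration(pats)),
               mean(g$ground_truth$bursts$duration), tolerance = 0.1)
})
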