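test_that("AAFT surrogates preserve amplitudes exactly and spectra closely", {
  set.seed(60)
  x <- as.numeric(arima.sim(list(ar = 0.95), 6000))    # coloured record
  s <- aaft_surrogate(x, seed = 1)
  expect_identical(sort(s), sort(x))                   # multiset equality
  expect_false(identical(s, x))
  # periodogram preserved on the log scale
  px <- log(Mod(fft(x - mean(x)))[2:3000]^2)
  ps <- log(Mod(fft(s - mean(s)))[2:3000]^2)
  sm <- function(v) stats::filter(v, rep(1 / 50, 50), sides = 2)
  r <- cor(na.omit(cbind(sm(px), sm(ps))))[1, 2]
  expect_gt(r, 0.9)
  expect_error(aaft_surrogate(rep(1, 100), 1), "constant")
  expect_error(aaft_surrogate(rnorm(10), 1), "too short")
  # determinism
  expect_identical(aaft_surrogate(x, seed = 7), aaft_surrogate(x, seed = 7))
})

test_that("independent surrogates of coupled channels are decorrelated", {
  r <- coherent_pair(100, 0.02, band("theta", 4, 8), 0.9, seed = 61)
  x <- r$samples[, 1]; y <- r$samples[, 2]
  expect_gt(abs(cor(x, y)), 0.5)
  cors <- vapply(1:20, function(k) {
    cor(aaft_surrogate(x, seed = 2 * k), aaft_surrogate(y, seed = 2 * k + 1))
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.1)
})

test_that("the surrogate test has the stated p-value convention", {
  # y identical to x: the observed correlation (1) beats every surrogate
  set.seed(64)
  x <- rnorm(256)
  st <- surrogate_test(function(x, y) cor(x, y), x, x, n_surr = 19, seed = 3)
  expect_equal(st$p_value, (1 + sum(st$surrogate_stats >= st$observed)) / 20)
  expect_equal(st$p_value, 0.05)
  # significance is strict (p < 0.05), so 19 surrogates can at best tie it
  expect_false(st$significant)
  expect_error(surrogate_test(cor, rnorm(100), rnorm(100), n_surr = 5),
               "n_surr")
})

test_that("the surrogate test detects genuine band coupling", {
  b <- band("theta", 4, 8)
  stat <- function(x, y) band_coherence(coherence(x, y, 0.02, window_s = 50,
                                                  overlap_s = 25,
                                                  daniell_hz = 0.2), b)
  hits <- vapply(1:25, function(k) {
    r <- coherent_pair(150, 0.02, b, 0.5, seed = 600 + k)
    surrogate_test(stat, r$samples[, 1], r$samples[, 2],
                   n_surr = 19, seed = k)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Mann-Whitney matches exhaustive enumeration for small groups", {
  expect_equal(mww_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mww_test(c(1, 2, 3, 7), c(1, 2, 3, 7)), 1)
  set.seed(62)
  for (k in 1:25) {
    na_ <- sample(3:5, 1); nb_ <- sample(3:5, 1)
    a <- round(rnorm(na_), 3); b <- round(rnorm(nb_) + 0.5, 3)
    if (any(duplicated(c(a, b)))) next
    expect_equal(mww_test(a, b), enum_mww(a, b), tolerance = 1e-12)
  }
  expect_error(mww_test(1:2, 1:5), "at least 3")
})

test_that("group summaries report mean and sd/sqrt(n)", {
  gs <- group_summary(list(a = c(2, 4, 6), b = c(5, 5, 5, 5)))
  expect_equal(gs$mean, c(4, 5))
  expect_equal(gs$sem[1], 2 / sqrt(3) * sqrt(3) / sqrt(3), tolerance = 1e-12)
  expect_equal(gs$sem[1], sd(c(2, 4, 6)) / sqrt(3))
  expect_equal(gs$sem[2], 0)
  expect_error(group_summary(list(a = 1)), "fewer than 2")
  # SEM of n standard-normal values averages sigma/sqrt(n)
  set.seed(63)
  sems <- replicate(1000, group_summary(list(g = rnorm(7)))$sem)
  expect_equal(mean(sems), 1 / sqrt(7), tolerance = 0.05)
})
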