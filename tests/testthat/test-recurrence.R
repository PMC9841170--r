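test_that("autocorrelation delay finds the first ACF minimum", {
  # sine of period P: first ACF minimum at P/2
  p <- 40
  x <- sin(2 * pi * seq_len(4000) / p)
  expect_equal(autocorr_delay(x, max_lag = 100), p / 2)
  # white noise: small delay (first negative fluctuation)
  set.seed(30)
  expect_lte(autocorr_delay(rnorm(5000), max_lag = 100), 5)
  expect_error(autocorr_delay(rep(1, 100)), "degenerate")
  expect_error(autocorr_delay(rnorm(100), max_lag = 60), "max_lag")
})

test_that("autocorrelation delay matches a brute-force ACF scan", {
  set.seed(31)
  for (phi in c(0.5, 0.9)) {
    x <- as.numeric(arima.sim(list(ar = phi), 3000))
    max_lag <- 200
    # independent oracle: same rule applied to a hand-computed ACF
    xc <- x - mean(x)
    a <- vapply(0:max_lag, function(l) {
      sum(xc[1:(3000 - l)] * xc[(1 + l):3000]) / sum(xc^2)
    }, numeric(1))
    expected <- NA
    for (l in 1:(max_lag - 1)) {
      if (a[l + 1] < a[l] && a[l + 1] < a[l + 2]) { expected <- l; break }
    }
    if (is.na(expected)) expected <- which(a[-1] <= 0)[1]
    expect_equal(autocorr_delay(x, max_lag = max_lag), expected)
  }
})

test_that("false-nearest-neighbour dimension behaves on canonical signals", {
  # noiseless sine: a circle, embedded cleanly in dimension 2
  x <- sin(2 * pi * seq_len(2000) / 25)
  m <- fnn_dimension(x, tau = 6, m_max = 5)
  expect_lte(as.integer(m), 2)
  expect_false(attr(m, "capped"))
  # white noise never unfolds: capped at m_max
  set.seed(32)
  mn <- fnn_dimension(rnorm(2000), tau = 1, m_max = 4, atol = 1)
  expect_true(attr(mn, "capped"))
  expect_error(fnn_dimension(rnorm(50), tau = 10, m_max = 8), "too short")
})

test_that("the Lorenz x-coordinate unfolds in three dimensions", {
  # RK4 integration of the Lorenz system (sigma 10, rho 28, beta 8/3)
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - 8 / 3 * s[3])
  h <- 0.02
  s <- c(1, 1, 20)
  xs <- numeric(4500)
  for (i in seq_len(4500)) {
    k1 <- f(s); k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    xs[i] <- s[1]
  }
  xs <- xs[-(1:500)]                       # drop the transient
  # conventional short delay (~0.1 s); the autocorrelation minimum of
  # Lorenz-x is far too long a delay for so strongly chaotic a signal
  expect_equal(as.integer(fnn_dimension(xs, tau = 5, m_max = 6)), 3)
})

test_that("delay embedding has the documented geometry", {
  expect_equal(delay_embed(1:10, 1, 1)[, 1], 1:10)
  tr <- delay_embed(1:10, 3, 2)
  expect_equal(dim(tr), c(6, 3))
  expect_equal(delay_embed(1:10, 2, 3)[1, ], c(1, 4))
  expect_error(delay_embed(1:5, 3, 3), "too short")
})

test_that("cross-recurrence matrix honours epsilon and the RR policy", {
  set.seed(33)
  tr <- delay_embed(rnorm(300), 3, 2)
  m <- cross_recurrence_matrix(tr, tr, eps = 0.5)
  expect_true(all(diag(m) == 1))
  far <- cross_recurrence_matrix(tr, tr + 100, eps = 0.5)
  expect_true(all(far == 0))
  mrr <- cross_recurrence_matrix(tr, delay_embed(rnorm(300), 3, 2),
                                 rr_target = 0.1)
  expect_lt(abs(mean(mrr) - 0.1), 0.005)
  expect_error(cross_recurrence_matrix(tr, tr[, 1:2]), "dimension mismatch")
})

test_that("diagonal indices agree exactly with the brute-force scanner", {
  set.seed(34)
  for (k in 1:100) {
    m <- matrix(rbinom(30 * 30, 1, runif(1, 0.05, 0.5)), 30, 30)
    got <- cra_indices(m)
    want <- brute_cra(m)
    for (nm in c("RR", "DET", "L", "MDL", "ENTR")) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
    }
  }
})

test_that("the compiled scanner matches the matrix path exactly", {
  set.seed(35)
  for (k in 1:20) {
    ta <- delay_embed(rnorm(120), 3, 2)
    tb <- delay_embed(rnorm(120), 3, 2)
    mat <- cross_recurrence_matrix(ta, tb, rr_target = 0.1)
    a <- cra_indices(mat)
    b <- cra_scan(ta, tb, rr_target = 0.1)
    for (nm in c("RR", "DET", "L", "MDL", "ENTR")) {
      expect_equal(a[[nm]], b[[nm]], tolerance = 1e-12, label = nm)
    }
    expect_equal(attr(mat, "eps"), b$params$eps, tolerance = 1e-12)
  }
})

test_that("index construction is symmetric and monotone in epsilon", {
  set.seed(36)
  ta <- delay_embed(rnorm(150), 3, 2)
  tb <- delay_embed(rnorm(150), 3, 2)
  m1 <- cross_recurrence_matrix(ta, tb, eps = 1)
  m2 <- cross_recurrence_matrix(tb, ta, eps = 1)
  expect_identical(unclass(m2), unclass(t(m1)), ignore_attr = TRUE)
  i1 <- cra_indices(m1); i2 <- cra_indices(m2)
  for (nm in c("RR", "DET", "L", "MDL", "ENTR")) {
    expect_equal(i1[[nm]], i2[[nm]], label = nm)
  }
  mdls <- vapply(c(0.5, 1, 2, 4), function(e) {
    cra_scan(ta, tb, eps = e)$MDL
  }, numeric(1))
  expect_true(all(diff(mdls) >= 0))
})

test_that("identical and shifted trajectories give the expected MDL", {
  x <- as.numeric(scale(cumsum(rnorm(200))))
  tr <- delay_embed(x, 2, 1)
  n <- nrow(tr)
  ident <- cra_indices(cross_recurrence_matrix(tr, tr, eps = 1e-9))
  expect_equal(ident$MDL, n)
  expect_equal(ident$DET, 1)
  s <- 30
  shifted <- cra_indices(cross_recurrence_matrix(
    tr, tr[(s + 1):n, ], eps = 1e-9))
  expect_equal(shifted$MDL, n - s)
})

test_that("band-limited CRA couples through a shared source", {
  set.seed(37)
  # identical channels: maximal diagonal spans the whole window
  x <- rnorm(30 / test_dt)
  ident <- cra_band_index(x, x, test_dt, "theta", "all",
                          analysis_hz = 25, window_s = 20)
  expect_equal(ident$MDL, 20 * 25 - (ident$m - 1) * ident$tau)
  # a coherent pair recurs more than an independent pair (paired seeds)
  wins <- vapply(1:8, function(k) {
    rc <- coherent_pair(120, test_dt, band("theta", 4, 8), 0.9, seed = 100 + k)
    ri <- coherent_pair(120, test_dt, band("theta", 4, 8), 0.0, seed = 200 + k)
    noise <- function(n) 0.3 * rnorm(n)
    n <- nrow(rc$samples)
    mc <- cra_band_index(rc$samples[, 1] + noise(n), rc$samples[, 2] + noise(n),
                         test_dt, "theta", "MDL", analysis_hz = 25, window_s = 60)
    mi <- cra_band_index(ri$samples[, 1] + noise(n), ri$samples[, 2] + noise(n),
                         test_dt, "theta", "MDL", analysis_hz = 25, window_s = 60)
    mc > mi
  }, logical(1))
  expect_gte(mean(wins), 7 / 8)
})
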