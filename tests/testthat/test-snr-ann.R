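test_that("the SNR series is mean-over-sd per window on a 1-s lattice", {
  # window {1, 2, 3}: mean 2, sd 1 -> SNR 2
  s <- snr_series(c(1, 2, 3), sampling_interval_s = 1, window_s = 3, step_s = 1)
  expect_equal(s$values, 2)
  # scale invariance for positive gain
  set.seed(50)
  x <- rnorm(3000) + 0.3
  s1 <- snr_series(x, 0.1, window_s = 60, step_s = 1)
  s2 <- snr_series(7.3 * x, 0.1, window_s = 60, step_s = 1)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
  expect_equal(length(s1$values), (300 - 60) / 1 + 1)
  expect_error(snr_series(rep(1, 100), 1, window_s = 10), "zero-variance")
  expect_error(snr_series(rnorm(10), 1, window_s = 60), "shorter")
})

test_that("a native-rate 60-s window holds 120,000 samples", {
  # 0.0005-s sampling: the 60-s SNR window covers exactly 120,000 points
  nw <- as.integer(round(60 / 0.0005))
  expect_identical(nw, 120000L)
  x <- rnorm(nw)                       # exactly one window long
  expect_length(snr_series(x, 0.0005)$values, 1)
  expect_error(snr_series(x[-1], 0.0005), "shorter")
})

test_that("fragments are 90 values spanning 1.5 minutes", {
  v <- rnorm(270)
  fr <- fragment_features(v)
  expect_equal(dim(fr), c(3, 90))
  expect_equal(fr[2, ], v[91:180])
  # at the 1-s SNR step, one fragment spans 90 s = 1.5 min
  expect_equal(90 * 1 / 60, 1.5)
  expect_error(fragment_features(rnorm(89)), "at least 90")
  expect_equal(nrow(fragment_features(rnorm(200), stride = 10)), 12)
})

test_that("training is deterministic and separates separable clusters", {
  set.seed(51)
  pos <- matrix(rnorm(20 * 90, mean = 1), 20)
  neg <- matrix(rnorm(20 * 90, mean = -1), 20)
  hp <- list(hidden = c(40, 10), epochs = 150)
  m1 <- train_detector(pos, neg, hp, seed = 9)
  m2 <- train_detector(pos, neg, hp, seed = 9)
  expect_identical(m1$W, m2$W)
  acc <- mean(c(network_response(m1, pos) > 0.5,
                network_response(m1, neg) < 0.5))
  expect_gte(acc, 0.95)
  expect_error(train_detector(pos[1:5, ], neg, hp), "at least 10")
})

test_that("responses are clamped to [0, 1] and validated", {
  set.seed(52)
  pos <- matrix(rnorm(15 * 90, 1), 15); neg <- matrix(rnorm(15 * 90, -1), 15)
  m <- train_detector(pos, neg, list(hidden = c(20, 5), epochs = 50), seed = 1)
  r <- network_response(m, matrix(rnorm(50 * 90, 0, 5), 50))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(network_response(m, rnorm(80)), "input size")
  # zero-weight model: constant clamped bias
  mz <- m
  for (l in seq_along(mz$W)) { mz$W[[l]][] <- 0; mz$b[[l]][] <- 0 }
  expect_equal(network_response(mz, matrix(rnorm(5 * 90), 5)), rep(0, 5))
})

test_that("Cs counts similar fragments and the literal ratio is exposed", {
  expect_equal(compute_cs(c(0.9, 0.8, 0.1, 0.2)), 0.5)
  expect_equal(compute_cs(rep(1, 10)), 1)
  expect_true(compute_cs(runif(50)) >= 0 && compute_cs(runif(50)) <= 1)
  # order invariance: a count statistic
  set.seed(53)
  r <- runif(40)
  expect_equal(compute_cs(r), compute_cs(sample(r)))
  expect_equal(cs_count_ratio(c(0.9, 0.8, 0.1, 0.2)), 1)
  expect_equal(cs_count_ratio(rep(0.9, 4)), Inf)
  expect_error(compute_cs(numeric(0)), "no responses")
})

test_that("shuffled labels erase the held-out class contrast", {
  set.seed(54)
  make <- function(mu, n = 30) matrix(rnorm(n * 90, mu, 1), n)
  hp <- list(hidden = c(30, 8), epochs = 80)
  dcs <- vapply(1:20, function(k) {
    pos <- make(0.8); neg <- make(-0.8)
    all_fr <- rbind(pos, neg)
    lab <- sample(rep(c(TRUE, FALSE), each = 30))
    m <- train_detector(all_fr[lab, ], all_fr[!lab, ], hp, seed = k)
    test_pos <- make(0.8, 15); test_neg <- make(-0.8, 15)
    compute_cs(network_response(m, test_pos)) -
      compute_cs(network_response(m, test_neg))
  }, numeric(1))
  expect_lt(abs(mean(dcs)), 0.1)
})

test_that("the leave-one-subject protocol transfers identical positives", {
  set.seed(55)
  pos_shared <- matrix(rnorm(12 * 90, 2), 12)
  frags <- lapply(1:4, function(s) {
    list(obbb = pos_shared, wake = matrix(rnorm(12 * 90, -2), 12))
  })
  names(frags) <- paste0("s", 1:4)
  res <- leave_one_subject_protocol(frags, hyperparams = list(
    hidden = c(30, 8), epochs = 250, patience = 60), seed = 5)
  cs_pos <- res$summary$mean_cs[res$summary$state == "obbb"]
  expect_gt(cs_pos, 0.95)
  expect_true(all(res$summary$mean_cs >= 0 & res$summary$mean_cs <= 1))
  expect_equal(sort(unique(res$per_network$train_subject)), paste0("s", 1:4))
  # a subject without both classes is skipped with a warning
  frags$s2$wake <- NULL
  expect_warning(
    leave_one_subject_protocol(frags, hyperparams = list(
      hidden = c(10, 4), epochs = 10), seed = 5), "skipped")
})
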