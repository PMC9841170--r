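# Independent oracles used across the suite. These deliberately use naive
# loop-based algorithms, separate from the package's implementations.

# Brute-force cross-recurrence diagonal scanner: walks every diagonal with an
# explicit loop and counts runs by hand.
brute_cra <- function(mat, lmin = 2) {
  na <- nrow(mat); nb <- ncol(mat)
  lines <- integer(0)
  mdl <- 0
  for (d in (-(nb - 1)):(na - 1)) {
    run <- 0
    for (j in seq_len(nb)) {
      i <- j + d
      inside <- i >= 1 && i <= na
      v <- if (inside) mat[i, j] else 0
      if (inside && v == 1) {
        run <- run + 1
      } else if (run > 0) {
        lines <- c(lines, run)
        run <- 0
      }
    }
    if (run > 0) lines <- c(lines, run)
  }
  keep <- lines[lines >= lmin]
  pts_all <- sum(lines)
  tab <- table(keep)
  p <- as.numeric(tab) / length(keep)
  list(
    RR = sum(mat) / (na * nb),
    DET = if (pts_all > 0) sum(keep) / pts_all else 0,
    L = if (length(keep) > 0) mean(keep) else 0,
    MDL = if (length(lines) > 0) max(lines) else 0,
    ENTR = if (length(keep) > 0) -sum(p * log(p)) else 0
  )
}

# Exhaustive Mann-Whitney enumeration: two-sided p-value from the exact
# permutation distribution of the rank sum (no ties assumed).
enum_mww <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na_ <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na_)]) - na_ * (na_ + 1) / 2
  combos <- utils::combn(n, na_)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na_ * (na_ + 1) / 2)
  mu <- na_ * (n - na_) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Reduced-rate settings used to keep simulated fixtures fast; all EEG content
# in the generator lives below 12.5 Hz.
test_dt <- 0.004   # 250 Hz

quiet_profiles <- function(dt = test_dt) default_profiles(dt)
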