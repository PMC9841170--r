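# Internal helpers: deterministic seeding, filtering, decimation.

#' Derive a per-subject random seed from a master seed
#'
#' Deterministic integer mixing (a Weyl/multiplicative scheme carried out in
#' double precision, exact below 2^53) so that cohorts are reproducible across
#' platforms independently of any host hash function. Result is in
#' `[1, 2^31 - 2]` and therefore always a valid R seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index (e.g. subject number).
#' @return an integer seed.
#' @export
mix_seed <- function(master, index = 0L) {
  m <- 2147483647               # 2^31 - 1 (prime)
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(index) * 16807 + 12345) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 1L) + 1L)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Zero-phase Butterworth band-pass. Degenerate low edges (<= 0) fall back to
# low-pass; high edges at/above Nyquist fall back to high-pass.
bandpass <- function(x, dt, f_lo, f_hi, order = 4) {
  fny <- 1 / (2 * dt)
  stopifnot(f_hi > f_lo)
  lo <- f_lo / fny
  hi <- f_hi / fny
  if (lo <= 0 && hi >= 1) return(x)
  if (lo <= 0) {
    bf <- signal::butter(order, hi, type = "low")
  } else if (hi >= 1) {
    bf <- signal::butter(order, lo, type = "high")
  } else {
    bf <- signal::butter(order, c(lo, hi), type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

# Anti-alias filtered decimation to a target rate (integer factor of 1/dt).
decimate_to <- function(x, dt, target_hz) {
  fs <- 1 / dt
  fac <- fs / target_hz
  if (abs(fac - round(fac)) > 1e-8) {
    stop("target rate must divide the sampling rate (", fs, " Hz)")
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  bf <- signal::butter(8, 0.8 / fac, type = "low")
  y <- as.numeric(signal::filtfilt(bf, x))
  y[seq(1L, length(y), by = fac)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
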