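# Welch power spectral density, Daniell frequency-domain smoothing, band
# power, cross-spectrum and the magnitude coherence function C(f).
#
# Estimation convention: 100-s segments with 50-s overlap, per-segment mean
# removal only (linear detrending would destroy the 0.1-Hz band of interest),
# Bartlett (triangular) taper against leakage, one-sided density normalised so
# the integral over [0, Nyquist] equals the signal variance. FFT length equals
# the segment length, so the grid spacing is 1/window_s (0.01 Hz by default)
# and the 0.03-Hz / 0.13-Hz Daniell windows are 3 and 13 bins.

welch_segments <- function(n, nseg, step) {
  if (n < nseg) stop("record shorter than one analysis window")
  k <- (n - nseg) %/% step + 1L
  (seq_len(k) - 1L) * step + 1L
}

bartlett_taper <- function(n) {
  i <- seq_len(n) - 1L
  1 - abs(2 * i / (n - 1) - 1)
}

# Per-segment tapered FFTs as a (nfreq x K) complex matrix plus metadata.
segment_ffts <- function(x, dt, window_s, overlap_s, taper) {
  nseg <- as.integer(round(window_s / dt))
  step <- as.integer(round((window_s - overlap_s) / dt))
  if (step <= 0) stop("overlap_s must be smaller than window_s")
  starts <- welch_segments(length(x), nseg, step)
  w <- switch(taper,
              bartlett = bartlett_taper(nseg),
              boxcar = rep(1, nseg),
              stop("unknown taper: ", taper))
  u <- mean(w^2)
  nf <- nseg %/% 2 + 1L
  f <- matrix(0i, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    f[, j] <- fft(seg)[seq_len(nf)]
  }
  list(f = f, nseg = nseg, u = u, k = length(starts),
       freqs = (seq_len(nf) - 1L) / window_s)
}

# One-sided density scaling: 2*dt/(nseg*U), with DC (and Nyquist for even
# nseg) not doubled.
onesided_scale <- function(nseg, u, dt) {
  nf <- nseg %/% 2 + 1L
  sc <- rep(2 * dt / (nseg * u), nf)
  sc[1] <- sc[1] / 2
  if (nseg %% 2 == 0) sc[nf] <- sc[nf] / 2
  sc
}

#' Welch power spectral density estimate
#'
#' @param x numeric signal.
#' @param sampling_interval_s seconds per sample.
#' @param window_s segment length in seconds (default 100).
#' @param overlap_s segment overlap in seconds (default 50).
#' @param taper `"bartlett"` (triangular, default) or `"boxcar"`.
#' @return an object of class `eeg_spectrum` with fields `frequencies` (Hz),
#'   `power` (units^2/Hz), and the estimation parameters.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 200, by = 0.01))
#' sp <- welch_psd(x, 0.01)
welch_psd <- function(x, sampling_interval_s, window_s = 100, overlap_s = 50,
                      taper = "bartlett") {
  dt <- sampling_interval_s
  sf <- segment_ffts(x, dt, window_s, overlap_s, taper)
  sc <- onesided_scale(sf$nseg, sf$u, dt)
  pwr <- rowMeans(Mod(sf$f)^2) * sc
  structure(
    list(frequencies = sf$freqs, power = pwr,
         params = list(window_s = window_s, overlap_s = overlap_s,
                       taper = taper, daniell_hz = 0, segments = sf$k,
                       sampling_interval_s = dt)),
    class = "eeg_spectrum"
  )
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d bins, 0-%.4g Hz (df=%.4g), %d segment(s)\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1], x$params$segments))
  invisible(x)
}

# Truncated centred running mean (works on numeric or complex vectors).
running_mean <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Daniell smoothing of a spectral estimate
#'
#' Replaces each spectral value by the unweighted mean over a centred
#' frequency window of the stated width (truncated at the grid edges).
#'
#' @param spectrum an `eeg_spectrum` from [welch_psd()].
#' @param bandwidth_hz width of the averaging window in Hz; must be at least
#'   the grid spacing.
#' @return the smoothed `eeg_spectrum`.
#' @export
daniell_smooth <- function(spectrum, bandwidth_hz) {
  df <- spectrum$frequencies[2] - spectrum$frequencies[1]
  if (bandwidth_hz < df - 1e-12) {
    stop("Daniell bandwidth (", bandwidth_hz, " Hz) is below the grid spacing (",
         df, " Hz)")
  }
  half <- max(0L, as.integer(round(bandwidth_hz / df)) %/% 2L)
  spectrum$power <- running_mean(spectrum$power, half)
  spectrum$params$daniell_hz <- bandwidth_hz
  spectrum
}

#' Band power by trapezoidal integration
#'
#' @param spectrum an `eeg_spectrum`.
#' @param band a [band()], band name, or `c(f_lo, f_hi)`; must lie within the
#'   spectrum's frequency span.
#' @return integrated power over the band (amplitude-squared units).
#' @export
band_power <- function(spectrum, band) {
  b <- as_band(band)
  f <- spectrum$frequencies
  if (b$f_lo < f[1] - 1e-12 || b$f_hi > f[length(f)] + 1e-12) {
    stop("band [", b$f_lo, ", ", b$f_hi, "] outside the spectrum span")
  }
  inside <- f > b$f_lo & f < b$f_hi
  fg <- c(b$f_lo, f[inside], b$f_hi)
  pg <- c(approx(f, spectrum$power, b$f_lo, rule = 2)$y,
          spectrum$power[inside],
          approx(f, spectrum$power, b$f_hi, rule = 2)$y)
  sum(diff(fg) * (head(pg, -1) + tail(pg, -1)) / 2)
}

#' Magnitude coherence function C(f)
#'
#' `C(f) = |Gxy(f)| / sqrt(Gxx(f) Gyy(f))`, with the auto- and cross-spectra
#' estimated by Welch segment averaging and then Daniell-smoothed *before*
#' forming the ratio (smoothing after the ratio with a single segment would
#' force C = 1 identically). Values are clipped to `[0, 1]` against
#' floating-point overshoot.
#'
#' @param x,y numeric signals of equal length.
#' @param sampling_interval_s seconds per sample.
#' @param window_s,overlap_s Welch segmentation (defaults 100 / 50 s).
#' @param daniell_hz Daniell window width for the spectra (default 0.13 Hz).
#' @param taper per-segment taper (default Bartlett).
#' @return object of class `eeg_coherence`: `frequencies`, `coherence`,
#'   `cross` (complex cross-spectral density), `K` segments, parameters.
#' @export
coherence <- function(x, y, sampling_interval_s, window_s = 100,
                      overlap_s = 50, daniell_hz = 0.13, taper = "bartlett") {
  if (length(x) != length(y)) stop("x and y must have the same length")
  dt <- sampling_interval_s
  fx <- segment_ffts(x, dt, window_s, overlap_s, taper)
  fy <- segment_ffts(y, dt, window_s, overlap_s, taper)
  k <- fx$k
  df <- 1 / window_s
  half <- max(0L, as.integer(round(daniell_hz / df)) %/% 2L)
  if (k < 2 && half < 1) {
    stop("degenerate coherence estimator: a single segment with no frequency ",
         "smoothing would give C(f) = 1 identically")
  }
  sc <- onesided_scale(fx$nseg, fx$u, dt)
  gxx <- rowMeans(Mod(fx$f)^2) * sc
  gyy <- rowMeans(Mod(fy$f)^2) * sc
  gxy <- rowMeans(fx$f * Conj(fy$f)) * sc
  if (half > 0) {
    gxx <- Re(running_mean(gxx, half))
    gyy <- Re(running_mean(gyy, half))
    gxy <- running_mean(gxy, half)
  }
  den <- sqrt(gxx * gyy)
  co <- ifelse(den > 0, Mod(gxy) / den, 0)
  co <- pmin(1, pmax(0, co))
  structure(
    list(frequencies = fx$freqs, coherence = co, cross = gxy, K = k,
         params = list(window_s = window_s, overlap_s = overlap_s,
                       daniell_hz = daniell_hz, taper = taper,
                       sampling_interval_s = dt)),
    class = "eeg_coherence"
  )
}

#' @export
print.eeg_coherence <- function(x, ...) {
  cat(sprintf("<eeg_coherence> %d bins, 0-%.4g Hz, K=%d segments, Daniell %.3g Hz\n",
              length(x$frequencies), max(x$frequencies), x$K, x$params$daniell_hz))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Unweighted mean of `C(f)` over the frequency bins inside the band.
#'
#' @param coherence_estimate an `eeg_coherence` from [coherence()].
#' @param band a [band()], band name, or `c(f_lo, f_hi)`.
#' @return scalar mean coherence.
#' @export
band_coherence <- function(coherence_estimate, band) {
  b <- as_band(band)
  f <- coherence_estimate$frequencies
  if (b$f_lo < f[1] - 1e-12 || b$f_hi > f[length(f)] + 1e-12) {
    stop("band [", b$f_lo, ", ", b$f_hi, "] outside the coherence span")
  }
  sel <- f >= b$f_lo & f <= b$f_hi
  mean(coherence_estimate$coherence[sel])
}
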