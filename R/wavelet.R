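# Continuous wavelet transform (Morlet), skeleton (ridge) extraction, and
# oscillatory-pattern detection yielding per-band pattern durations T.
#
# The transform follows the standard FFT implementation with the analytic
# Morlet mother (centre frequency omega0 = 6, the field default for EEG
# rhythm analysis) and an energy normalisation chosen so that the
# time-averaged power surface of white noise is flat in frequency.

morlet_fourier_factor <- function(omega0 = 6) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous wavelet transform
#'
#' @param x numeric signal.
#' @param sampling_interval_s seconds per sample.
#' @param freqs analysis frequencies (Hz), strictly increasing, within
#'   `(0, Nyquist]`. Default: 30 log-spaced voices over 0.05--30 Hz (clipped
#'   to Nyquist).
#' @param omega0 Morlet centre frequency (default 6).
#' @return object of class `eeg_cwt`: `frequencies`, `times` (s), `power`
#'   (`|W|^2`, frequencies x times), `coi_freq` (per time, the frequency
#'   below which edge effects dominate: the cone of influence).
#' @export
cwt <- function(x, sampling_interval_s, freqs = NULL, omega0 = 6) {
  dt <- sampling_interval_s
  ny <- 1 / (2 * dt)
  if (is.null(freqs)) {
    freqs <- exp(seq(log(0.05), log(min(30, ny)), length.out = 30))
  }
  if (length(freqs) == 0) stop("empty frequency grid")
  if (any(freqs <= 0) || any(freqs > ny + 1e-9)) {
    stop("analysis frequencies must lie in (0, Nyquist]")
  }
  n <- length(x)
  ff <- morlet_fourier_factor(omega0)
  scales <- 1 / (ff * freqs)
  xf <- fft(x - mean(x))
  omega <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dt)
  pow <- matrix(0, length(freqs), n)
  norm0 <- pi^(-1 / 4)
  for (k in seq_along(freqs)) {
    s <- scales[k]
    psi <- numeric(n)
    pos <- omega > 0
    psi[pos] <- norm0 * exp(-(s * omega[pos] - omega0)^2 / 2)
    # sqrt(2*pi*s/dt): unit-energy scaling => flat white-noise expectation
    w <- fft(xf * psi * sqrt(2 * pi * s / dt), inverse = TRUE) / n
    pow[k, ] <- Mod(w)^2
  }
  t <- (seq_len(n) - 1L) * dt
  edge <- pmax(pmin(t, (n - 1) * dt - t), dt)
  coi_freq <- sqrt(2) / (ff * edge)  # e-folding time sqrt(2)*s
  structure(
    list(frequencies = freqs, times = t, power = pow, coi_freq = coi_freq,
         params = list(omega0 = omega0, sampling_interval_s = dt)),
    class = "eeg_cwt"
  )
}

#' @export
print.eeg_cwt <- function(x, ...) {
  cat(sprintf("<eeg_cwt> %d frequencies (%.3g-%.3g Hz) x %d times (%.1f s)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times), max(x$times)))
  invisible(x)
}

#' Skeleton (ridge set) of a wavelet power surface
#'
#' For each time column, the frequencies of local power maxima (across
#' frequency) exceeding `floor_power` are taken; maxima in consecutive
#' columns within one frequency step are linked into ridges.
#'
#' @param surface an `eeg_cwt` from [cwt()].
#' @param floor_power ridge points below this power are discarded (default 0:
#'   keep all local maxima; pattern detection applies its own floor).
#' @return list of ridges; each ridge is a data.frame with `time_index`,
#'   `time_s`, `freq_index`, `freq_hz`, `power`.
#' @export
skeleton <- function(surface, floor_power = 0) {
  p <- surface$power
  nf <- nrow(p); nt <- ncol(p)
  if (nf < 3) stop("need at least 3 frequency voices for ridge extraction")
  is_max <- rbind(FALSE, p[2:(nf - 1), , drop = FALSE] >=
                    p[1:(nf - 2), , drop = FALSE] &
                    p[2:(nf - 1), , drop = FALSE] >
                    p[3:nf, , drop = FALSE], FALSE) &
    p > floor_power
  ridges <- list()
  active <- list()   # open ridges: list(freq_index, rows)
  for (t in seq_len(nt)) {
    fidx <- which(is_max[, t])
    used <- logical(length(fidx))
    nxt <- list()
    for (a in active) {
      hit <- which(!used & abs(fidx - a$last) <= 1L)
      if (length(hit)) {
        j <- hit[which.min(abs(fidx[hit] - a$last))]
        used[j] <- TRUE
        a$rows[[length(a$rows) + 1L]] <- c(t, fidx[j])
        a$last <- fidx[j]
        nxt[[length(nxt) + 1L]] <- a
      } else {
        ridges[[length(ridges) + 1L]] <- a$rows
      }
    }
    for (j in which(!used)) {
      nxt[[length(nxt) + 1L]] <- list(last = fidx[j], rows = list(c(t, fidx[j])))
    }
    active <- nxt
  }
  for (a in active) ridges[[length(ridges) + 1L]] <- a$rows
  lapply(ridges, function(rows) {
    m <- do.call(rbind, rows)
    data.frame(time_index = m[, 1],
               time_s = surface$times[m[, 1]],
               freq_index = m[, 2],
               freq_hz = surface$frequencies[m[, 2]],
               power = p[cbind(m[, 2], m[, 1])])
  })
}

#' Detect oscillatory patterns in a band
#'
#' Maximal ridge segments whose frequency stays inside `band` and whose power
#' stays at or above `power_floor`; segments separated by gaps shorter than
#' `merge_gap_s` are merged (narrowband carriers fluctuate, and a momentary
#' power dip does not end an oscillatory event); segments shorter than
#' `min_duration_s` are discarded.
#'
#' @param ridges ridge list from [skeleton()].
#' @param band a [band()], band name, or `c(f_lo, f_hi)`.
#' @param surface the `eeg_cwt` the ridges came from (for the floor default
#'   and the time step).
#' @param power_floor absolute power threshold, either a scalar or one value
#'   per frequency voice; default `k_floor` times the per-voice median power
#'   (a per-frequency noise floor, so that leakage from strong neighbouring
#'   bands does not mask in-band events), bounded below by `k_floor` times
#'   the pooled in-band median.
#' @param k_floor multiplier for the median-based default floor (default 2.5,
#'   calibrated so threshold-crossing durations match known event durations).
#' @param min_duration_s minimal event duration; default two cycles of the
#'   band centre frequency.
#' @param merge_gap_s events separated by less than this are merged (0.3 s).
#' @return object of class `eeg_patterns`: data.frame of events (`band`,
#'   `t_start`, `t_end`, `duration`, `peak_freq_hz`) plus parameters.
#' @export
detect_patterns <- function(ridges, band, surface, power_floor = NULL,
                            k_floor = 2.5, min_duration_s = NULL,
                            merge_gap_s = 0.3) {
  b <- as_band(band)
  fc <- (b$f_lo + b$f_hi) / 2
  min_duration_s <- min_duration_s %||% (2 / fc)
  sel_f <- surface$frequencies >= b$f_lo & surface$frequencies <= b$f_hi
  if (!any(sel_f)) stop("no analysis frequencies inside the band")
  if (is.null(power_floor)) {
    # per-voice noise floor, bounded below by the pooled in-band median so
    # that voices with little background do not admit arbitrarily weak tails
    vmed <- apply(surface$power, 1, median)
    gmed <- median(surface$power[sel_f, ])
    power_floor <- k_floor * pmax(vmed, gmed)
  }
  floor_of <- if (length(power_floor) == 1L) {
    function(fi) power_floor
  } else {
    function(fi) power_floor[fi]
  }
  dt_col <- if (length(surface$times) > 1)
    surface$times[2] - surface$times[1] else 1

  events <- list()
  for (r in ridges) {
    ok <- r$freq_hz >= b$f_lo & r$freq_hz <= b$f_hi &
      r$power >= floor_of(r$freq_index)
    if (!any(ok)) next
    rr <- rle(ok)
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    for (i in which(rr$values)) {
      seg <- r[starts[i]:ends[i], ]
      events[[length(events) + 1L]] <-
        data.frame(t_start = seg$time_s[1],
                   t_end = seg$time_s[nrow(seg)] + dt_col,
                   peak_freq_hz = seg$freq_hz[which.max(seg$power)],
                   peak_power = max(seg$power))
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(t_start = numeric(0), t_end = numeric(0),
               peak_freq_hz = numeric(0), peak_power = numeric(0))
  ev <- ev[order(ev$t_start), , drop = FALSE]
  # merge across short gaps (ridges may also briefly hand over between voices)
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      last <- nrow(merged)
      if (ev$t_start[i] - merged$t_end[last] < merge_gap_s) {
        merged$t_end[last] <- max(merged$t_end[last], ev$t_end[i])
        if (ev$peak_power[i] > merged$peak_power[last]) {
          merged$peak_power[last] <- ev$peak_power[i]
          merged$peak_freq_hz[last] <- ev$peak_freq_hz[i]
        }
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  ev$duration <- ev$t_end - ev$t_start
  ev <- ev[ev$duration >= min_duration_s, , drop = FALSE]
  rownames(ev) <- NULL
  ev$band <- rep(b$name, nrow(ev))
  structure(
    list(events = ev[, c("band", "t_start", "t_end", "duration",
                         "peak_freq_hz")],
         params = list(band = b, power_floor = power_floor,
                       min_duration_s = min_duration_s,
                       merge_gap_s = merge_gap_s)),
    class = "eeg_patterns"
  )
}

#' @export
print.eeg_patterns <- function(x, ...) {
  cat(sprintf("<eeg_patterns> %d event(s) in %s, mean T = %.3f s\n",
              nrow(x$events), x$params$band$name, mean_duration(x)))
  invisible(x)
}

#' Mean pattern duration T-bar
#'
#' @param pattern_set an `eeg_patterns` from [detect_patterns()].
#' @return arithmetic mean of event durations (s); 0 with attribute
#'   `empty = TRUE` when there are no events.
#' @export
mean_duration <- function(pattern_set) {
  d <- pattern_set$events$duration
  if (length(d) == 0) return(structure(0, empty = TRUE))
  mean(d)
}

#' Band pattern durations for a raw channel
#'
#' Convenience wrapper: decimate, transform (frequency grid spanning an
#' octave around the band), extract the skeleton and detect in-band patterns.
#'
#' @param x numeric signal.
#' @param sampling_interval_s seconds per sample.
#' @param band a [band()], band name, or `c(f_lo, f_hi)`.
#' @param analysis_hz decimation target (default 25 Hz).
#' @param n_voices frequency voices across the extended grid (default 20).
#' @param smooth_s moving-average time smoothing of the power surface before
#'   ridge extraction (default 0.3 s), which stabilises the fluctuating power
#'   of stochastic narrowband carriers.
#' @param ... passed to [detect_patterns()].
#' @return an `eeg_patterns` object.
#' @export
band_patterns <- function(x, sampling_interval_s, band, analysis_hz = 25,
                          n_voices = 20, smooth_s = 0.3, ...) {
  b <- as_band(band)
  xd <- decimate_to(x, sampling_interval_s, analysis_hz)
  ny <- analysis_hz / 2
  f_lo <- max(b$f_lo / 1.6, 0.02)
  f_hi <- min(b$f_hi * 1.6, ny * 0.99)
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n_voices))
  surf <- cwt(xd, 1 / analysis_hz, freqs = freqs)
  if (smooth_s > 0) {
    dtc <- surf$times[2] - surf$times[1]
    half <- as.integer(round(smooth_s / dtc)) %/% 2L
    if (half > 0) {
      surf$power <- t(apply(surf$power, 1, running_mean, half = half))
    }
  }
  detect_patterns(skeleton(surf), b, surf, ...)
}
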