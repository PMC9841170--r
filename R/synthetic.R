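# Synthetic three-state rat EEG/EMG cohort generator.
#
# Each state is a superposition of band-limited Gaussian processes plus a
# 1/f background, with the structure (which components are shared between the
# two EEG leads, how regular/narrowband the theta process is) chosen so that
# the linear (coherence, band power) and non-linear (cross-recurrence, wavelet
# pattern, SNR/ANN) contrasts between wakefulness, NREM-dominated sleep and
# blood-brain-barrier opening (OBBB) can all be expressed with known ground
# truth.

#' State profile for the synthetic EEG generator
#'
#' Describes one brain state as a set of band-limited components. Component
#' variances are given in absolute (arbitrary) amplitude-squared units; the
#' corresponding variance *fractions* (relative to the total including the 1/f
#' background) are computed and validated to sum to at most 1.
#'
#' @param state_name one of `"wake"`, `"sleep"`, `"obbb"` (free-form allowed).
#' @param band_powers named numeric vector of component variances (units^2).
#'   Recognised components: `infraslow` (0.005--0.03 Hz), `delta_slow`
#'   (0.1--0.5 Hz), `delta_wide` (0.5--4 Hz), `theta` (see `theta_band`),
#'   `alpha` (8--12 Hz).
#' @param theta_coherence target magnitude coherence of the two EEG leads in
#'   the theta band, in `[0, 1]`.
#' @param slow_power_boost variance (units^2) of the narrow 0.08--0.12 Hz
#'   "slow" oscillation shared by both leads; the hallmark OBBB component.
#' @param emg_tone RMS amplitude of the (white-noise) EMG channel, > 0.
#' @param burst_mean_duration_s mean duration (s) of exponential theta bursts.
#' @param noise_power variance of the per-lead independent 1/f background.
#' @param theta_band theta process band edges (Hz).
#' @param theta_narrow_frac fraction of the theta power carried by a
#'   narrowband (more regular, slowly decorrelating) sub-process; 0 gives the
#'   fully broadband desynchronised theta of wakefulness.
#' @param theta_narrow_band band edges of the narrow theta sub-process (Hz),
#'   inside `theta_band`.
#' @param burst_duty long-run fraction of time spent inside a theta burst
#'   (used only when `burst_gap_s` is `NULL`).
#' @param burst_gap_s mean inter-burst gap in seconds; when set (default 2 s
#'   in the shipped profiles) the duty cycle follows from the burst mean
#'   duration, so states with longer bursts do not also get longer quiet
#'   periods.
#' @param burst_power_ratio instantaneous theta power ratio burst on / off.
#' @param sync named numeric in `[0, 1]`: the fraction of the `delta_slow` /
#'   `delta_wide` component variance shared between the two leads
#'   (synchronised EEG ~ 1, desynchronised ~ 0). Logical values are accepted
#'   (`TRUE` = 1, `FALSE` = 0).
#' @param coh_calibration empirical attenuation of the theta-band-averaged
#'   measured coherence relative to the internal mixing coefficient
#'   (`NULL` = analytic flat-spectrum value; the default profiles carry
#'   empirically measured constants, which also absorb the spectral
#'   broadening of the narrow theta peak by the burst envelope).
#' @param slow_osc_sync fraction of the 0.08--0.12 Hz slow-oscillation
#'   variance shared between the leads (1 for the globally synchronised OBBB
#'   oscillation, 0 for independent residual slow activity).
#' @param burst_coh_cap upper bound on the within-burst mixing coefficient;
#'   coherence demand beyond the cap is carried by the inter-burst floor.
#'   Keeping bursts below full coherence prevents single high-coherence
#'   subjects from producing burst-length recurrence runs.
#' @param burst_sync do theta bursts occur simultaneously on both leads
#'   (`TRUE`, synchronised bursting typical of sleep-like states) or with
#'   independent timing per lead (`FALSE`, desynchronised wakefulness)?
#' @param stage_label ground-truth hypnogram label for this state
#'   (`"wake"`, `"NREM"` or `"REM"`).
#' @param subject_sd named list of between-subject standard deviations applied
#'   by [generate_cohort()]: `theta_coherence` (additive), `delta_slow_power`
#'   (additive, on the measured 0.1--0.5 Hz power), `burst_cv` and `emg_cv`
#'   (multiplicative coefficients of variation).
#' @return an object of class `eeg_state_profile`.
#' @export
state_profile <- function(state_name,
                          band_powers,
                          theta_coherence,
                          slow_power_boost = 1,
                          emg_tone = 1,
                          burst_mean_duration_s = 1.2,
                          noise_power = 3,
                          theta_band = c(4, 8),
                          theta_narrow_frac = 0,
                          theta_narrow_band = c(5.2, 6.8),
                          burst_duty = 0.35,
                          burst_gap_s = NULL,
                          burst_power_ratio = 9,
                          sync = c(delta_slow = 1, delta_wide = 1),
                          coh_calibration = NULL,
                          burst_coh_cap = 1,
                          slow_osc_sync = 1,
                          burst_sync = TRUE,
                          stage_label = "wake",
                          subject_sd = list()) {
  stopifnot(is.numeric(band_powers), !is.null(names(band_powers)))
  known <- c("infraslow", "delta_slow", "delta_wide", "theta", "alpha")
  if (!all(names(band_powers) %in% known)) {
    stop("unknown component(s): ",
         paste(setdiff(names(band_powers), known), collapse = ", "))
  }
  if (any(band_powers < 0)) stop("component variances must be >= 0")
  if (!(theta_coherence >= 0 && theta_coherence <= 1)) {
    stop("theta_coherence must be in [0, 1]")
  }
  if (slow_power_boost < 0) stop("slow_power_boost must be >= 0")
  if (emg_tone <= 0) stop("emg_tone must be > 0")
  if (burst_mean_duration_s <= 0) stop("burst_mean_duration_s must be > 0")
  if (noise_power < 0) stop("noise_power must be >= 0")
  if (!(burst_duty > 0 && burst_duty < 1)) stop("burst_duty must be in (0, 1)")
  if (!(theta_narrow_frac >= 0 && theta_narrow_frac <= 1)) {
    stop("theta_narrow_frac must be in [0, 1]")
  }
  if (theta_narrow_band[1] < theta_band[1] || theta_narrow_band[2] > theta_band[2]) {
    stop("theta_narrow_band must lie inside theta_band")
  }
  if (!stage_label %in% c("wake", "NREM", "REM")) {
    stop("stage_label must be one of wake/NREM/REM")
  }
  sync <- vapply(sync, as.numeric, numeric(1))
  if (any(sync < 0 | sync > 1)) stop("sync fractions must be in [0, 1]")
  if (slow_osc_sync < 0 || slow_osc_sync > 1) stop("slow_osc_sync must be in [0, 1]")
  total <- sum(band_powers) + slow_power_boost + noise_power
  fractions <- c(band_powers, slow_osc = slow_power_boost) / total
  if (sum(fractions) > 1 + 1e-9) stop("band-power fractions exceed 1") # cannot happen
  sd_default <- list(theta_coherence = 0, delta_slow_power = 0,
                     burst_cv = 0, emg_cv = 0)
  sd_default[names(subject_sd)] <- subject_sd
  structure(
    list(state_name = state_name, band_powers = band_powers,
         band_fractions = fractions, theta_coherence = theta_coherence,
         slow_power_boost = slow_power_boost, emg_tone = emg_tone,
         burst_mean_duration_s = burst_mean_duration_s,
         noise_power = noise_power, theta_band = theta_band,
         theta_narrow_frac = theta_narrow_frac,
         theta_narrow_band = theta_narrow_band,
         burst_duty = burst_duty, burst_gap_s = burst_gap_s,
         burst_power_ratio = burst_power_ratio,
         sync = sync, coh_calibration = coh_calibration,
         burst_coh_cap = burst_coh_cap,
         slow_osc_sync = slow_osc_sync,
         burst_sync = isTRUE(burst_sync),
         stage_label = stage_label, subject_sd = sd_default),
    class = "eeg_state_profile"
  )
}

#' @export
print.eeg_state_profile <- function(x, ...) {
  cat(sprintf("<state_profile> %s: theta C=%.2f (%g-%g Hz), slow boost=%.2f, EMG=%.2f, burst T=%.2f s\n",
              x$state_name, x$theta_coherence, x$theta_band[1], x$theta_band[2],
              x$slow_power_boost, x$emg_tone, x$burst_mean_duration_s))
  invisible(x)
}

# Integral of the 1/f background spectrum over [f_lo, f_hi], as a fraction of
# its total variance. The background is S(f) ~ 1/f on [f0, Nyquist], flat
# below the knee f0 = 0.05 Hz (so the infra-slow band is owned by the
# state-dependent infraslow component, not the background).
noise_band_fraction <- function(f_lo, f_hi, nyquist, f0 = 0.05) {
  denom <- 1 + log(nyquist / f0)
  flat <- max(0, min(f_hi, f0) - max(f_lo, 0)) / f0
  lo <- max(f_lo, f0); hi <- min(f_hi, nyquist)
  lg <- if (hi > lo) log(hi / lo) else 0
  (flat + lg) / denom
}

#' Expected measured band power of a generated recording
#'
#' Oracle helper: the band power (units^2) that [welch_psd()] + [band_power()]
#' should recover from one EEG lead of a recording generated from `profile`,
#' i.e. the in-band parts of all structured components plus the 1/f
#' background contribution.
#'
#' @param profile a [state_profile()].
#' @param band a [band()], band name, or `c(f_lo, f_hi)`.
#' @param sampling_interval_s sampling interval used for generation.
#' @return expected band power in amplitude-squared units.
#' @export
expected_band_power <- function(profile, band, sampling_interval_s = 5e-4) {
  b <- as_band(band)
  ny <- 1 / (2 * sampling_interval_s)
  comp_bands <- list(
    infraslow  = c(0.005, 0.03),
    delta_slow = c(0.1, 0.5),
    delta_wide = c(0.5, 4),
    theta      = profile$theta_band,
    alpha      = c(8, 12)
  )
  p <- 0
  for (nm in names(profile$band_powers)) {
    cb <- comp_bands[[nm]]
    ov <- max(0, min(b$f_hi, cb[2]) - max(b$f_lo, cb[1])) / (cb[2] - cb[1])
    p <- p + profile$band_powers[[nm]] * ov
  }
  ov_slow <- max(0, min(b$f_hi, 0.12) - max(b$f_lo, 0.08)) / 0.04
  p <- p + profile$slow_power_boost * ov_slow
  p + profile$noise_power * noise_band_fraction(b$f_lo, b$f_hi, ny)
}

#' Default three-state profiles
#'
#' Wake, sleep (NREM-dominated) and OBBB profiles whose injected targets are
#' the published group means: theta coherence 0.68 / 0.52 / 0.53, measured
#' 0.1--0.5 Hz band power 4.91 / 3.84 / 11.85 units^2, mean theta-burst
#' durations 1.47 / 1.18 / 1.16 s. Wakefulness is desynchronised
#' (independent-per-lead delta, broadband theta, high EMG tone); sleep and
#' OBBB are synchronised (shared delta, narrowband theta, low EMG); OBBB
#' additionally carries the strong shared 0.08--0.12 Hz slow oscillation and
#' the largest infra-slow activity.
#'
#' @param sampling_interval_s sampling interval the delta-slow calibration
#'   assumes (only the small 1/f in-band contribution depends on it).
#' @return named list of three [state_profile()] objects.
#' @export
default_profiles <- function(sampling_interval_s = 5e-4) {
  ny <- 1 / (2 * sampling_interval_s)
  noise_power <- 3
  nb <- noise_power * noise_band_fraction(0.1, 0.5, ny)
  # delta_slow component variance solved so the measured 0.1-0.5 Hz band power
  # hits the published target: target = delta_slow + 0.5*slow_osc + background.
  dslow <- function(target, boost) max(0, target - 0.5 * boost - nb)
  list(
    wake = state_profile(
      "wake",
      band_powers = c(infraslow = 0.08, delta_slow = dslow(4.91, 1),
                      delta_wide = 1.5, theta = 2.5, alpha = 2.0),
      theta_coherence = 0.68, slow_power_boost = 1, emg_tone = 3.0,
      burst_mean_duration_s = 1.47, burst_gap_s = 2,
      burst_power_ratio = 14, noise_power = noise_power,
      theta_band = c(4, 8), coh_calibration = 0.901, burst_coh_cap = 0.85,
      sync = c(delta_slow = 0.15, delta_wide = 0.15), slow_osc_sync = 0,
      burst_sync = TRUE,
      stage_label = "wake",
      subject_sd = list(theta_coherence = 0.026, delta_slow_power = 0.159,
                        burst_cv = 0.05, emg_cv = 0.05)
    ),
    sleep = state_profile(
      "sleep",
      band_powers = c(infraslow = 2.0, delta_slow = dslow(3.84, 1),
                      delta_wide = 8.0, theta = 3.0, alpha = 0.3),
      theta_coherence = 0.52, slow_power_boost = 1, emg_tone = 1.0,
      burst_mean_duration_s = 1.18, burst_gap_s = 2, noise_power = noise_power,
      theta_band = c(4, 8), theta_narrow_frac = 0.95,
      theta_narrow_band = c(5.85, 6.15), coh_calibration = 1.13,
      sync = c(delta_slow = 0.8, delta_wide = 0.8), burst_sync = TRUE,
      stage_label = "NREM",
      subject_sd = list(theta_coherence = 0.026, delta_slow_power = 0.053,
                        burst_cv = 0.05, emg_cv = 0.05)
    ),
    obbb = state_profile(
      "obbb",
      band_powers = c(infraslow = 4.0, delta_slow = dslow(11.85, 16),
                      delta_wide = 8.0, theta = 3.0, alpha = 0.3),
      theta_coherence = 0.53, slow_power_boost = 16, emg_tone = 1.2,
      burst_mean_duration_s = 1.16, burst_gap_s = 2, noise_power = noise_power,
      theta_band = c(4, 8), theta_narrow_frac = 0.95,
      theta_narrow_band = c(5.85, 6.15), coh_calibration = 1.13,
      sync = c(delta_slow = 0.85, delta_wide = 0.85), burst_sync = TRUE,
      stage_label = "wake",
      subject_sd = list(theta_coherence = 0.053, delta_slow_power = 0.66,
                        burst_cv = 0.05, emg_cv = 0.05)
    )
  )
}

# --- spectral-synthesis primitives ------------------------------------------

# Band-limited Gaussian signal with exactly unit variance, synthesised in the
# frequency domain (flat spectrum inside [f_lo, f_hi], zero outside).
rand_band_signal <- function(n, dt, f_lo, f_hi) {
  freqs <- seq(0, 1 / (2 * dt), by = 1 / (n * dt))[seq_len(n %/% 2 + 1)]
  amp <- as.numeric(freqs > f_lo & freqs <= f_hi)
  if (sum(amp) < 2) {
    # band narrower than the frequency resolution: use the nearest bin
    amp <- as.numeric(abs(freqs - (f_lo + f_hi) / 2) ==
                        min(abs(freqs - (f_lo + f_hi) / 2)))
  }
  synth_from_amplitude(n, amp)
}

# 1/f^alpha background, unit variance, flat below f0.
rand_pink_signal <- function(n, dt, alpha = 1, f0 = 0.05) {
  freqs <- seq(0, 1 / (2 * dt), by = 1 / (n * dt))[seq_len(n %/% 2 + 1)]
  s <- numeric(length(freqs))
  s[-1] <- 1 / pmax(freqs[-1], f0)^alpha
  synth_from_amplitude(n, sqrt(s))
}

# Hermitian-symmetric random-phase synthesis from a half-spectrum amplitude.
synth_from_amplitude <- function(n, amp) {
  nh <- n %/% 2 + 1
  z <- complex(real = rnorm(nh), imaginary = rnorm(nh)) * amp
  z[1] <- 0
  if (n %% 2 == 0) z[nh] <- complex(real = rnorm(1), imaginary = 0) * amp[nh]
  full <- c(z, Conj(rev(z[2:(nh - 1L + n %% 2)])))[seq_len(n)]
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop("degenerate synthesised signal (empty band?)")
  x / s
}

# Theta-burst envelope: shifted-exponential on-durations (minimum 0.4 s - an
# oscillatory event needs a couple of cycles to exist - with overall mean =
# mean_dur) separated by exponential gaps tuned to the requested duty cycle;
# smoothed with a 0.2-s moving average; normalised to unit mean square.
# Returns the envelope and the ground-truth burst interval table.
burst_envelope <- function(n, dt, mean_dur, duty, power_ratio, min_dur = 0.4,
                           mean_gap = NULL) {
  len_s <- n * dt
  if (is.null(mean_gap)) mean_gap <- mean_dur * (1 - duty) / duty
  duty <- mean_dur / (mean_dur + mean_gap)
  d0 <- min(min_dur, 0.5 * mean_dur)
  starts <- c(); ends <- c()
  # start mid-gap so records do not all open with a burst edge
  t <- rexp(1, 1 / mean_gap)
  while (t < len_s) {
    d <- d0 + rexp(1, 1 / (mean_dur - d0))
    s0 <- t; e0 <- min(t + d, len_s)
    starts <- c(starts, s0); ends <- c(ends, e0)
    t <- e0 + rexp(1, 1 / mean_gap)
  }
  env <- numeric(n)
  if (length(starts)) {
    i0 <- pmax(1L, as.integer(floor(starts / dt)) + 1L)
    i1 <- pmin(n, as.integer(ceiling(ends / dt)))
    for (k in seq_along(i0)) env[i0[k]:i1[k]] <- 1
  }
  # 0.2-s raised edges via moving average (cumsum trick)
  w <- max(1L, as.integer(round(0.2 / dt)))
  cs <- cumsum(c(0, env))
  sm <- (cs[pmin(n + 1L, seq_len(n) + w %/% 2L + 1L)] -
           cs[pmax(1L, seq_len(n) - w %/% 2L)]) / w
  a_off2 <- 1 / (duty * power_ratio + (1 - duty))
  a_on2 <- power_ratio * a_off2
  a <- sqrt(a_off2) + (sqrt(a_on2) - sqrt(a_off2)) * sm
  a <- a / sqrt(mean(a^2))
  list(envelope = a,
       bursts = data.frame(start = starts, end = ends,
                           duration = ends - starts))
}

# --- public generator operations --------------------------------------------

#' Two channels with a prescribed in-band magnitude coherence
#'
#' Builds `x = sqrt(c) s + sqrt(1-c) n1`, `y = sqrt(c) s + sqrt(1-c) n2` from
#' three independent band-limited unit-variance processes, so the population
#' magnitude coherence inside `band` equals `target_coherence` (and is
#' undefined/zero outside, where there is no power).
#'
#' @param length_s record length in seconds.
#' @param sampling_interval_s seconds per sample.
#' @param band a [band()] (or name / `c(f_lo, f_hi)`) within the Nyquist range.
#' @param target_coherence desired coherence in `[0, 1]`.
#' @param seed integer seed.
#' @return an [recording()] with channels `EEG-L`, `EEG-R`.
#' @export
#' @examples
#' r <- coherent_pair(200, 0.002, band("theta", 4, 8), 0.5, seed = 1)
coherent_pair <- function(length_s, sampling_interval_s, band,
                          target_coherence, seed) {
  b <- as_band(band)
  ny <- 1 / (2 * sampling_interval_s)
  if (!(target_coherence >= 0 && target_coherence <= 1)) {
    stop("target_coherence must be in [0, 1]")
  }
  if (b$f_hi > ny) stop("band exceeds the Nyquist frequency (", ny, " Hz)")
  n <- as.integer(round(length_s / sampling_interval_s))
  with_seed(seed, {
    s  <- rand_band_signal(n, sampling_interval_s, b$f_lo, b$f_hi)
    n1 <- rand_band_signal(n, sampling_interval_s, b$f_lo, b$f_hi)
    n2 <- rand_band_signal(n, sampling_interval_s, b$f_lo, b$f_hi)
    cc <- target_coherence
    x <- sqrt(cc) * s + sqrt(1 - cc) * n1
    y <- sqrt(cc) * s + sqrt(1 - cc) * n2
    recording(cbind(x, y), sampling_interval_s,
              channel_labels = c("EEG-L", "EEG-R"),
              subject_id = "coherent_pair")
  })
}

#' Generate one synthetic recording with ground truth
#'
#' Produces a three-channel (EEG-L, EEG-R, EMG) recording from a
#' [state_profile()]: a coherent theta pair (amplitude-modulated by shared
#' exponential-duration bursts), shared or independent delta components
#' including the 0.08--0.12 Hz slow oscillation, an infra-slow component, a
#' per-lead 1/f background, and a white-noise EMG. The theta mixing
#' coefficient is inflated internally so that the *measured* theta-band
#' coherence (which also sees the 1/f background inside 4--8 Hz) matches
#' `profile$theta_coherence`.
#'
#' @param profile a [state_profile()].
#' @param length_s record length in seconds (>= 600 recommended, so at least
#'   one Welch window fits several times over).
#' @param seed integer seed; identical `(profile, length_s, seed)` gives a
#'   bit-identical recording.
#' @param sampling_interval_s seconds per sample (default 0.0005).
#' @return list with elements `recording` ([recording()]) and `ground_truth`
#'   (injected theta coherence, expected delta-slow band power, burst table,
#'   per-10-s-epoch stage labels, component variances).
#' @export
generate_recording <- function(profile, length_s, seed,
                               sampling_interval_s = 5e-4) {
  if (!inherits(profile, "eeg_state_profile")) stop("profile must be a state_profile")
  if (length_s <= 0) stop("length_s must be > 0")
  dt <- sampling_interval_s
  ny <- 1 / (2 * dt)
  n <- as.integer(round(length_s / dt))
  bp <- profile$band_powers
  gv <- function(nm) if (nm %in% names(bp)) bp[[nm]] else 0

  # Coherence mixing coefficient solved so the *band-averaged* measured
  # coherence over theta_band equals the target: per frequency
  # C(f) = c_mix * p(f) / (p(f) + n(f)) with flat component densities and the
  # 1/f background density n(f); averaging analytically over the broad and
  # narrow sub-regions gives the attenuation A, and c_mix = target / A.
  p_theta <- gv("theta")
  tb <- profile$theta_band
  nb <- profile$theta_narrow_band
  eta <- profile$theta_narrow_frac
  c_target <- profile$theta_coherence
  c_mix <- 0
  if (p_theta > 0) {
    w_broad <- tb[2] - tb[1]
    w_nar <- nb[2] - nb[1]
    p_b <- p_theta * (1 - eta) / w_broad
    p_e <- if (eta > 0) p_theta * eta / w_nar else 0
    nden <- function(lo, hi) {     # mean 1/f background density over [lo, hi]
      profile$noise_power * noise_band_fraction(lo, hi, ny) / (hi - lo)
    }
    n_out <- nden(tb[1], tb[2])
    n_nar <- nden(nb[1], nb[2])
    A <- ((w_broad - w_nar) * p_b / (p_b + n_out) +
            w_nar * (p_b + p_e) / (p_b + p_e + n_nar)) / w_broad
    if (!is.null(profile$coh_calibration)) A <- profile$coh_calibration
    c_mix <- c_target / A
    if (c_mix > 1) {
      stop("theta_coherence ", c_target, " unreachable: background power in ",
           "the theta band is too large relative to the theta component")
    }
  }

  with_seed(seed, {
    eegL <- numeric(n); eegR <- numeric(n)

    if (p_theta > 0) {
      # shared source and per-lead noises, each with the same broad+narrow
      # spectral shape so C(f) is flat at c_mix across the theta component
      theta_proc <- function() {
        x <- sqrt(1 - eta) * rand_band_signal(n, dt, tb[1], tb[2])
        if (eta > 0) x <- x + sqrt(eta) * rand_band_signal(n, dt, nb[1], nb[2])
        x
      }
      # Inter-lead theta coherence is carried by the synchronised bursts
      # (coherent theta trains); the inter-burst theta floor is independent
      # per lead. The burst mixing c_b is inflated so the overall measured
      # band coherence (quiet + burst periods pooled) hits the target:
      # shared fraction = c_b * beta with beta the burst share of theta power.
      # Burst carriers are broadband in every state (so wavelet event
      # detection behaves identically across states); the state-specific
      # narrowness (theta_narrow_frac) lives in the quiet floor, where it
      # sets how slowly the independent floors decorrelate.
      broad_proc <- function() rand_band_signal(n, dt, tb[1], tb[2])
      s <- broad_proc(); n1 <- broad_proc(); n2 <- broad_proc()
      sq_ <- theta_proc(); u1 <- theta_proc(); u2 <- theta_proc()
      beL <- burst_envelope(n, dt, profile$burst_mean_duration_s,
                            profile$burst_duty, profile$burst_power_ratio,
                            mean_gap = profile$burst_gap_s)
      if (profile$burst_sync) {
        beR <- beL
      } else {
        beR <- burst_envelope(n, dt, profile$burst_mean_duration_s,
                              profile$burst_duty, profile$burst_power_ratio,
                              mean_gap = profile$burst_gap_s)
      }
      a_off <- min(beL$envelope, beR$envelope)
      beta <- 1 - a_off^2                       # burst share of theta power
      c_b <- min(profile$burst_coh_cap %||% 1, c_mix / beta)
      # overflow (targets unreachable through bursts alone) is carried by a
      # small coherent fraction of the inter-burst floor
      c_q <- max(0, (c_mix - beta * c_b) / (1 - beta))
      if (c_q > 1) {
        stop("theta_coherence ", c_target, " unreachable in this construction")
      }
      gL <- sqrt(pmax(0, beL$envelope^2 - a_off^2))
      gR <- sqrt(pmax(0, beR$envelope^2 - a_off^2))
      sq <- sqrt(p_theta)
      qs <- sqrt(c_q); qn <- sqrt(1 - c_q)
      eegL <- eegL + sq * (a_off * (qs * sq_ + qn * u1) +
                             gL * (sqrt(c_b) * s + sqrt(1 - c_b) * n1))
      eegR <- eegR + sq * (a_off * (qs * sq_ + qn * u2) +
                             gR * (sqrt(c_b) * s + sqrt(1 - c_b) * n2))
      bursts <- beL$bursts
      bursts_right <- beR$bursts
    } else {
      bursts <- data.frame(start = numeric(0), end = numeric(0),
                           duration = numeric(0))
      bursts_right <- bursts
    }

    add_component <- function(f_lo, f_hi, v, share = 1) {
      if (v <= 0) return(invisible())
      if (share > 0) {
        x <- rand_band_signal(n, dt, f_lo, f_hi) * sqrt(v * share)
        eegL <<- eegL + x; eegR <<- eegR + x
      }
      if (share < 1) {
        eegL <<- eegL + rand_band_signal(n, dt, f_lo, f_hi) * sqrt(v * (1 - share))
        eegR <<- eegR + rand_band_signal(n, dt, f_lo, f_hi) * sqrt(v * (1 - share))
      }
    }
    add_component(0.005, 0.03, gv("infraslow"), share = 1)
    add_component(0.08, 0.12, profile$slow_power_boost,
                  share = profile$slow_osc_sync %||% 1)
    add_component(0.1, 0.5, gv("delta_slow"),
                  share = profile$sync[["delta_slow"]])
    add_component(0.5, 4, gv("delta_wide"),
                  share = profile$sync[["delta_wide"]])
    add_component(8, 12, gv("alpha"), share = 0)
    if (profile$noise_power > 0) {
      eegL <- eegL + rand_pink_signal(n, dt) * sqrt(profile$noise_power)
      eegR <- eegR + rand_pink_signal(n, dt) * sqrt(profile$noise_power)
    }
    emg <- rnorm(n) * profile$emg_tone

    rec <- recording(cbind(eegL, eegR, emg), dt,
                     channel_labels = c("EEG-L", "EEG-R", "EMG"),
                     subject_id = paste0(profile$state_name, "_1"),
                     state = profile$state_name)
    n_ep <- floor(length_s / 10)
    gt <- list(
      theta_coherence = c_target,
      delta_slow_power = expected_band_power(profile, "delta_slow", dt),
      bursts = bursts,
      bursts_right = bursts_right,
      burst_mean_duration_s = profile$burst_mean_duration_s,
      stage_labels = rep(profile$stage_label, n_ep),
      band_powers = bp,
      emg_tone = profile$emg_tone
    )
    list(recording = rec, ground_truth = gt)
  })
}

# Between-subject jitter: a deterministic per-subject perturbation of the
# injected targets (see state_profile()$subject_sd).
jitter_profile <- function(profile, seed, sampling_interval_s = 5e-4) {
  sdl <- profile$subject_sd
  with_seed(seed, {
    p <- profile
    p$theta_coherence <- min(1, max(0, profile$theta_coherence +
                                      rnorm(1, 0, sdl$theta_coherence)))
    if (sdl$delta_slow_power > 0) {
      delta <- rnorm(1, 0, sdl$delta_slow_power)
      p$band_powers[["delta_slow"]] <-
        max(0, profile$band_powers[["delta_slow"]] + delta)
    }
    if (sdl$burst_cv > 0) {
      p$burst_mean_duration_s <-
        profile$burst_mean_duration_s * exp(rnorm(1, 0, sdl$burst_cv))
    }
    if (sdl$emg_cv > 0) {
      p$emg_tone <- profile$emg_tone * exp(rnorm(1, 0, sdl$emg_cv))
    }
    p
  })
}

#' Generate a synthetic cohort
#'
#' One recording per subject per state profile, with deterministic per-subject
#' seeds derived from the master seed via [mix_seed()] and per-subject
#' between-subject variability applied to the injected targets.
#'
#' @param profiles named list of [state_profile()]s (e.g. [default_profiles()]).
#' @param n_per_group subjects per state (>= 2).
#' @param length_s record length per subject (s).
#' @param seed master integer seed.
#' @param sampling_interval_s seconds per sample.
#' @return list of `list(recording, ground_truth)` entries; subject ids are
#'   `"<state>_<i>"` and unique.
#' @export
generate_cohort <- function(profiles, n_per_group = 7, length_s = 600, seed = 1,
                            sampling_interval_s = 5e-4) {
  if (length(profiles) == 0) stop("profiles must be a non-empty list")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  out <- list()
  k <- 0L
  for (g in seq_along(profiles)) {
    prof <- profiles[[g]]
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      s_jit <- mix_seed(seed, 1000L * g + i)
      s_gen <- mix_seed(seed, 1000L * g + i + 500L)
      pj <- jitter_profile(prof, s_jit, sampling_interval_s)
      ri <- generate_recording(pj, length_s, s_gen, sampling_interval_s)
      ri$recording$subject_id <- paste0(prof$state_name, "_", i)
      ri$ground_truth$subject_id <- ri$recording$subject_id
      ri$ground_truth$state <- prof$state_name
      out[[k]] <- ri
    }
  }
  names(out) <- vapply(out, function(r) r$recording$subject_id, character(1))
  out
}

#' Build state profiles from a configuration list
#'
#' Turns a named list (e.g. the `profiles:` section of a YAML pipeline
#' configuration) into [state_profile()] objects; each entry is a list whose
#' fields are the `state_profile()` arguments (`band_powers` as a named list
#' or vector). Fields that are omitted keep their defaults.
#'
#' @param spec named list of profile descriptions.
#' @return named list of [state_profile()] objects.
#' @export
#' @examples
#' profiles_from_config(list(
#'   quiet = list(band_powers = c(theta = 2), theta_coherence = 0.5)
#' ))
profiles_from_config <- function(spec) {
  if (length(spec) == 0 || is.null(names(spec))) {
    stop("profile configuration must be a named list")
  }
  out <- lapply(names(spec), function(nm) {
    args <- spec[[nm]]
    args$band_powers <- unlist(args$band_powers)
    if (!is.null(args$sync)) args$sync <- unlist(args$sync)
    args$state_name <- args$state_name %||% nm
    do.call(state_profile, args)
  })
  names(out) <- names(spec)
  out
}
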