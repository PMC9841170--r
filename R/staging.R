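# Rule-based sleep staging of 10-s epochs, implementing the visual scoring
# criteria for rodents: wakefulness = desynchronised EEG with >10% of power at
# 8-12 Hz and relatively high EMG; NREM = delta (0-4 Hz) dominated (>30%) with
# lower EMG; REM = theta (5-10 Hz) > 20% with low EMG.
#
# "% of EEG waveforms/epoch" is visual-scoring language with no computable
# definition; it is interpreted here as the spectral power fraction of the
# epoch periodogram. "High/low EMG" is quantified as the epoch EMG RMS above /
# below a threshold (by default the per-recording median EMG RMS; any absolute
# threshold, e.g. a cohort-wide median, can be supplied instead).

#' Default staging thresholds
#'
#' @return list with `alpha_frac` (wake 8--12 Hz fraction, 0.10),
#'   `delta_frac` (NREM 0--4 Hz fraction, 0.30), `theta_frac`
#'   (REM 5--10 Hz fraction, 0.20).
#' @export
staging_thresholds <- function() {
  list(alpha_frac = 0.10, delta_frac = 0.30, theta_frac = 0.20)
}

#' Spectral-fraction and EMG features of one staging epoch
#'
#' @param eeg_epoch numeric EEG samples of a 10-s epoch.
#' @param emg_epoch numeric EMG samples of the same epoch.
#' @param sampling_interval_s seconds per sample.
#' @param epoch_s expected epoch duration (default 10 s); a mismatch is an error.
#' @return list with `delta_frac` (0--4 Hz), `theta_frac` (5--10 Hz),
#'   `alpha_frac` (8--12 Hz) power fractions and `emg_rms`.
#' @export
epoch_features <- function(eeg_epoch, emg_epoch, sampling_interval_s,
                           epoch_s = 10) {
  n <- length(eeg_epoch)
  if (abs(n * sampling_interval_s - epoch_s) > sampling_interval_s) {
    stop("epoch duration is ", n * sampling_interval_s, " s; expected ", epoch_s, " s")
  }
  x <- eeg_epoch - mean(eeg_epoch)
  nf <- n %/% 2 + 1L
  freqs <- (seq_len(nf) - 1L) / (n * sampling_interval_s)
  p <- Mod(fft(x)[seq_len(nf)])^2
  p[1] <- 0                       # DC removed with the mean
  tot <- sum(p)
  frac <- function(lo, hi) if (tot > 0) sum(p[freqs > lo & freqs <= hi]) / tot else 0
  list(delta_frac = frac(0, 4),
       theta_frac = frac(5, 10),
       alpha_frac = frac(8, 12),
       emg_rms = sqrt(mean(emg_epoch^2)))
}

#' Score one epoch from its features
#'
#' Decision cascade: high EMG and 8--12 Hz fraction > 10% gives WAKE; else
#' delta fraction > 30% with low EMG gives NREM; else theta (5--10 Hz)
#' fraction > 20% with low EMG gives REM; otherwise UNSCORED (which
#' [score_recording()] resolves to the previous epoch's label).
#'
#' @param features list from [epoch_features()].
#' @param emg_threshold EMG RMS above this value counts as "high EMG".
#' @param thresholds list from [staging_thresholds()].
#' @return one of `"WAKE"`, `"NREM"`, `"REM"`, `"UNSCORED"`.
#' @export
score_epoch <- function(features, emg_threshold,
                        thresholds = staging_thresholds()) {
  high_emg <- features$emg_rms > emg_threshold
  if (high_emg && features$alpha_frac > thresholds$alpha_frac) return("WAKE")
  if (!high_emg && features$delta_frac > thresholds$delta_frac) return("NREM")
  if (!high_emg && features$theta_frac > thresholds$theta_frac) return("REM")
  "UNSCORED"
}

#' Score a whole recording into a hypnogram
#'
#' One label per consecutive non-overlapping 10-s epoch. UNSCORED epochs
#' inherit the previous epoch's label (the first epoch defaults to WAKE).
#'
#' @param rec an [recording()] with at least one EEG channel and an `EMG`
#'   channel.
#' @param eeg_channel EEG channel label used for the spectral features
#'   (default the first non-EMG channel).
#' @param emg_threshold absolute EMG RMS threshold; default is the median
#'   epoch EMG RMS of this recording.
#' @param thresholds list from [staging_thresholds()].
#' @param epoch_s epoch length in seconds (default 10).
#' @return data.frame with `epoch`, `start_s`, `label` and the epoch features.
#' @export
score_recording <- function(rec, eeg_channel = NULL, emg_threshold = NULL,
                            thresholds = staging_thresholds(), epoch_s = 10) {
  if (!"EMG" %in% rec$channel_labels) stop("recording has no EMG channel")
  eeg_channel <- eeg_channel %||% eeg_labels(rec)[1]
  if (is.na(eeg_channel)) stop("recording has no EEG channel")
  eps <- epochize(rec, epoch_s = epoch_s)
  feats <- lapply(eps, function(e) {
    epoch_features(e$samples[, eeg_channel], e$samples[, "EMG"],
                   e$sampling_interval_s, epoch_s = epoch_s)
  })
  emg_rms <- vapply(feats, `[[`, 0, "emg_rms")
  emg_threshold <- emg_threshold %||% median(emg_rms)
  raw <- vapply(feats, score_epoch, "", emg_threshold = emg_threshold,
                thresholds = thresholds)
  lab <- character(length(raw))
  prev <- "WAKE"
  for (i in seq_along(raw)) {
    lab[i] <- if (raw[i] == "UNSCORED") prev else raw[i]
    prev <- lab[i]
  }
  data.frame(
    epoch = seq_along(lab),
    start_s = vapply(eps, `[[`, 0, "start_s"),
    label = lab,
    raw_label = raw,
    delta_frac = vapply(feats, `[[`, 0, "delta_frac"),
    theta_frac = vapply(feats, `[[`, 0, "theta_frac"),
    alpha_frac = vapply(feats, `[[`, 0, "alpha_frac"),
    emg_rms = emg_rms
  )
}
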