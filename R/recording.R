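#' Multichannel EEG/EMG recording
#'
#' Container for a regularly sampled multichannel recording. Samples are stored
#' time-by-channel (one column per channel) in arbitrary amplitude units.
#'
#' @param samples numeric matrix, rows = samples, columns = channels.
#' @param sampling_interval_s seconds per sample (default 0.0005, i.e. 2000 Hz).
#' @param channel_labels character vector, one label per column. Defaults to
#'   `EEG-L`, `EEG-R`, `EMG` for three channels.
#' @param subject_id subject identifier.
#' @param state optional state name (e.g. `"wake"`).
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, sampling_interval_s = 5e-4,
                      channel_labels = NULL, subject_id = "subject", state = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1L) stop("samples must be a numeric matrix")
  if (!(is.numeric(sampling_interval_s) && sampling_interval_s > 0)) {
    stop("sampling_interval_s must be > 0")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (ncol(samples) == 3L) c("EEG-L", "EEG-R", "EMG") else
      paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("channel_labels length must equal the number of channels")
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_interval_s = sampling_interval_s,
         channel_labels = channel_labels, subject_id = subject_id, state = state),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s%s: %d channels (%s), %.1f s at %g Hz\n",
              x$subject_id,
              if (is.null(x$state)) "" else paste0(" [", x$state, "]"),
              ncol(x$samples), paste(x$channel_labels, collapse = ", "),
              nrow(x$samples) * x$sampling_interval_s, 1 / x$sampling_interval_s))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$samples) * rec$sampling_interval_s

# Fetch a channel by label (or index), with a clear error.
rec_channel <- function(rec, which) {
  if (is.character(which)) {
    j <- match(which, rec$channel_labels)
    if (is.na(j)) stop("no channel labelled '", which, "' in recording")
  } else j <- which
  rec$samples[, j]
}

# EEG channel labels = everything that is not EMG.
eeg_labels <- function(rec) setdiff(rec$channel_labels, "EMG")
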