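# Recording I/O: a diffable CSV dialect and a minimal EDF (European Data
# Format) reader/writer, plus epoch slicing.
#
# CSV dialect: one comment line carrying the sampling interval and metadata,
# one header row of channel labels, one column per channel.
# EDF: standard 256 + ns*256 byte ASCII header and 16-bit little-endian data
# records (1-s records); the physical range is auto-scaled per channel, so a
# round trip is exact only to 16-bit quantisation.

#' Write a recording to disk
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @param format `"csv"` or `"edf"`; default inferred from the file extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         csv = write_recording_csv(rec, path),
         edf = write_recording_edf(rec, path),
         stop("unsupported format: ", format))
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path input file path.
#' @param format `"csv"` or `"edf"`; default inferred from the file extension.
#' @return an [recording()].
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         csv = read_recording_csv(path),
         edf = read_recording_edf(path),
         stop("unsupported format: ", format))
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_interval_s=%.12g subject_id=%s state=%s",
                     rec$sampling_interval_s, rec$subject_id,
                     rec$state %||% "NA"), con)
  writeLines(paste(rec$channel_labels, collapse = ","), con)
  utils::write.table(format(rec$samples, digits = 15, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_recording_csv <- function(path) {
  first <- readLines(path, n = 2L)
  if (length(first) < 2L || !startsWith(first[1], "#")) {
    stop("malformed recording CSV: missing metadata comment line")
  }
  meta <- regmatches(first[1], gregexpr("[a-z_]+=[^ ]+", first[1]))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  dt <- as.numeric(vals[["sampling_interval_s"]])
  if (!is.finite(dt) || dt <= 0) stop("malformed sampling interval in CSV header")
  labels <- strsplit(first[2], ",")[[1]]
  dat <- utils::read.csv(path, skip = 1L, header = TRUE,
                         col.names = labels, check.names = FALSE)
  m <- as.matrix(dat)
  if (!is.numeric(m) || anyNA(m)) stop("malformed recording CSV: non-numeric samples")
  st <- vals[["state"]]
  recording(m, dt, channel_labels = labels,
            subject_id = vals[["subject_id"]] %||% "subject",
            state = if (identical(st, "NA")) NULL else st)
}

# --- EDF --------------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  fs <- 1 / rec$sampling_interval_s
  if (abs(fs - round(fs)) > 1e-6) {
    stop("EDF writer requires an integer sampling rate (got ", fs, " Hz)")
  }
  spr <- as.integer(round(fs))           # samples per 1-s data record
  ns <- ncol(rec$samples)
  nrec <- nrow(rec$samples) %/% spr
  if (nrec < 1L) stop("recording shorter than one 1-s EDF data record")
  phys_min <- apply(rec$samples, 2, min)
  phys_max <- apply(rec$samples, 2, max)
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste0("state=", rec$state %||% "NA"), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste(edf_pad(rec$channel_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(formatC(phys_min, format = "g", digits = 6), 8), collapse = ""),
    paste(edf_pad(formatC(phys_max, format = "g", digits = 6), 8), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # re-read the header's printed physical range so scaling is self-consistent
  pmin_h <- as.numeric(formatC(phys_min, format = "g", digits = 6))
  pmax_h <- as.numeric(formatC(phys_max, format = "g", digits = 6))
  gain <- (pmax_h - pmin_h) / (dig_max - dig_min)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns)) {
      dig <- round((rec$samples[rows, j] - pmin_h[j]) / gain[j]) + dig_min
      writeBin(as.integer(pmin(dig_max, pmax(dig_min, dig))), con,
               size = 2L, endian = "little")
    }
  }
}

read_edf_field <- function(con, width, n = 1L) {
  trimws(vapply(seq_len(n), function(i) readChar(con, width, useBytes = TRUE),
                character(1)))
}

read_recording_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 256) stop("malformed EDF: file shorter than the fixed header")
  read_edf_field(con, 8)                      # version
  subject_id <- read_edf_field(con, 80)
  recfield <- read_edf_field(con, 80)
  read_edf_field(con, 8); read_edf_field(con, 8)
  hdr_bytes <- as.integer(read_edf_field(con, 8))
  read_edf_field(con, 44)
  nrec <- as.integer(read_edf_field(con, 8))
  dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (anyNA(c(hdr_bytes, nrec, dur, ns)) || ns < 1L) {
    stop("malformed EDF header")
  }
  labels <- read_edf_field(con, 16, ns)
  read_edf_field(con, 80, ns); read_edf_field(con, 8, ns)
  pmin <- as.numeric(read_edf_field(con, 8, ns))
  pmax <- as.numeric(read_edf_field(con, 8, ns))
  dmin <- as.numeric(read_edf_field(con, 8, ns))
  dmax <- as.numeric(read_edf_field(con, 8, ns))
  read_edf_field(con, 80, ns)
  spr <- as.integer(read_edf_field(con, 8, ns))
  read_edf_field(con, 32, ns)
  if (length(unique(spr)) != 1L) {
    stop("EDF with per-signal sampling rates is not supported")
  }
  expected <- hdr_bytes + nrec * sum(spr) * 2
  if (sz < expected) {
    stop("malformed EDF: file truncated (", sz, " bytes, expected ", expected, ")")
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, nrec * spr[1], ns)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2L,
                     endian = "little", signed = TRUE)
      out[((r - 1L) * spr[1] + 1L):(r * spr[1]), j] <-
        pmin[j] + (dig - dmin[j]) * gain[j]
    }
  }
  state <- sub("^state=", "", recfield)
  recording(out, dur / spr[1], channel_labels = labels,
            subject_id = subject_id,
            state = if (state %in% c("", "NA")) NULL else state)
}

# --- epoching ---------------------------------------------------------------

#' Slice a recording into (possibly overlapping) epochs
#'
#' Epochs start at `0, step_s, 2*step_s, ...` seconds (half-open intervals);
#' a trailing partial epoch is discarded.
#'
#' @param rec an [recording()].
#' @param epoch_s epoch duration in seconds (default 10, the staging epoch).
#' @param step_s spacing between epoch starts (default `epoch_s`,
#'   i.e. non-overlapping).
#' @param channels optional channel subset (labels or indices).
#' @return list of `eeg_epoch` objects with fields `start_s`, `duration_s`,
#'   `samples`, `channel_labels`, `sampling_interval_s`.
#' @export
#' @examples
#' r <- recording(matrix(rnorm(3000), ncol = 3), 0.01)
#' length(epochize(r, 2))  # 5 epochs of 2 s
epochize <- function(rec, epoch_s = 10, step_s = epoch_s, channels = NULL) {
  if (epoch_s <= 0) stop("epoch_s must be > 0")
  if (step_s <= 0) stop("step_s must be > 0")
  dt <- rec$sampling_interval_s
  nep <- as.integer(round(epoch_s / dt))
  nstep <- as.integer(round(step_s / dt))
  n <- nrow(rec$samples)
  if (nep > n) stop("epoch_s (", epoch_s, " s) exceeds the record length")
  cols <- if (is.null(channels)) seq_len(ncol(rec$samples)) else {
    if (is.character(channels)) match(channels, rec$channel_labels) else channels
  }
  if (anyNA(cols)) stop("unknown channel in subset")
  starts <- seq(1L, n - nep + 1L, by = nstep)
  lapply(starts, function(s) {
    structure(
      list(start_s = (s - 1L) * dt, duration_s = epoch_s,
           samples = rec$samples[s:(s + nep - 1L), cols, drop = FALSE],
           channel_labels = rec$channel_labels[cols],
           sampling_interval_s = dt),
      class = "eeg_epoch"
    )
  })
}
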