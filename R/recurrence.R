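# Takens delay embedding (autocorrelation-minimum delay, false-nearest-
# neighbour dimension) and cross-recurrence analysis (CRA).
#
# CRA projects the phase portraits of two signals into the same state space
# and marks pairs of trajectory points closer than epsilon. Diagonal-line
# structure of the resulting binary matrix quantifies stretches of jointly
# recurrent dynamics; the headline index is the maximal diagonal length (MDL).
# Beyond MDL, the standard recurrence-quantification set is reported (RR,
# DET, L, ENTR); these follow the conventional definitions.

#' Embedding delay from the autocorrelation function
#'
#' Returns the lag (samples) of the first local minimum of the sample
#' autocorrelation; if no local minimum occurs below `max_lag`, the first
#' zero crossing; if neither, `max_lag` with a warning.
#'
#' @param x numeric signal.
#' @param max_lag maximum lag to scan (samples), `< length(x) / 2`.
#' @return integer lag in samples.
#' @export
autocorr_delay <- function(x, max_lag = floor(length(x) / 4)) {
  if (max_lag >= length(x) / 2) stop("max_lag must be < length(x) / 2")
  if (sd(x) == 0) stop("degenerate input: constant signal has no autocorrelation delay")
  a <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)  # a[1] = lag 0
  for (lag in seq_len(max_lag - 1L)) {
    if (a[lag + 1L] < a[lag] && a[lag + 1L] < a[lag + 2L]) return(lag)
  }
  zc <- which(a[-1] <= 0)
  if (length(zc)) return(zc[1])
  warning("no autocorrelation minimum or zero crossing below max_lag; using max_lag")
  as.integer(max_lag)
}

#' Embedding dimension by false nearest neighbours
#'
#' Smallest dimension `m` whose false-neighbour fraction (Kennel criterion:
#' neighbour-distance growth beyond `rtol`, or post-embedding distance beyond
#' `atol` signal standard deviations) drops below `threshold`.
#'
#' @param x numeric signal.
#' @param tau embedding delay in samples.
#' @param m_max largest dimension to try.
#' @param rtol,atol Kennel tolerances (defaults 10 and 2).
#' @param theiler temporal exclusion window for the neighbour search
#'   (default `tau`), so trajectory-adjacent points do not count as
#'   neighbours.
#' @param threshold false-neighbour fraction considered negligible (0.01).
#' @return integer dimension, with attributes `fractions` (per dimension) and
#'   `capped` (`TRUE` if `m_max` was reached without passing the threshold).
#' @export
fnn_dimension <- function(x, tau, m_max = 8, rtol = 10, atol = 2,
                          theiler = tau, threshold = 0.01) {
  if (length(x) <= (m_max + 1) * tau + 10) {
    stop("signal too short for the requested embedding (need > ",
         (m_max + 1) * tau + 10, " samples)")
  }
  fr <- .fnn_fractions_cpp(as.numeric(x), as.integer(tau),
                           as.integer(m_max), rtol, atol, as.integer(theiler))
  ok <- which(!is.na(fr) & fr < threshold)
  m <- if (length(ok)) ok[1] else m_max
  structure(as.integer(m), fractions = fr, capped = length(ok) == 0)
}

#' Delay embedding
#'
#' Point `i` of the trajectory is
#' `(x[i], x[i + tau], ..., x[i + (m-1) tau])`.
#'
#' @param x numeric signal.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return numeric matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @export
#' @examples
#' delay_embed(1:10, m = 2, tau = 3)[1, ]  # (1, 4)
delay_embed <- function(x, m, tau) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("need m >= 1 and tau >= 1")
  np <- length(x) - (m - 1L) * tau
  if (np < 1L) stop("signal too short: need length > (m-1)*tau")
  out <- matrix(0, np, m)
  for (k in seq_len(m)) out[, k] <- x[(1L + (k - 1L) * tau):(np + (k - 1L) * tau)]
  out
}

#' Cross-recurrence matrix
#'
#' Entry `(i, j)` is 1 iff the Euclidean distance between trajectory points
#' `A_i` and `B_j` is at most epsilon. Epsilon is either fixed (`eps`) or
#' chosen as the `rr_target` quantile of all pairwise distances (default: a
#' fixed 10% recurrence rate).
#'
#' @param trajA,trajB trajectory matrices (rows = points) of equal dimension.
#' @param eps fixed epsilon, or `NULL` (default) for the fixed-RR policy.
#' @param rr_target target recurrence rate for the quantile policy.
#' @return binary integer matrix with attribute `eps`.
#' @export
cross_recurrence_matrix <- function(trajA, trajB, eps = NULL, rr_target = 0.1) {
  trajA <- as.matrix(trajA); trajB <- as.matrix(trajB)
  if (ncol(trajA) != ncol(trajB)) stop("trajectory dimension mismatch")
  # per-dimension differences (exact for coincident points, unlike the
  # cross-product expansion, which loses precision to cancellation)
  d2 <- matrix(0, nrow(trajA), nrow(trajB))
  for (k in seq_len(ncol(trajA))) {
    d2 <- d2 + outer(trajA[, k], trajB[, k], `-`)^2
  }
  if (is.null(eps)) {
    eps <- sqrt(quantile(d2, rr_target, names = FALSE, type = 1))
  }
  m <- matrix(as.integer(sqrt(d2) <= eps), nrow(trajA), nrow(trajB))
  attr(m, "eps") <- eps
  m
}

#' Diagonal-line indices of a cross-recurrence matrix
#'
#' Builds the histogram of diagonal line lengths (runs of ones along all
#' diagonals) and returns: `RR` (recurrence rate), `DET` (fraction of
#' recurrent points on diagonals of length >= `lmin`), `L` (mean diagonal
#' length among lines >= `lmin`), `MDL` (maximal diagonal length, samples),
#' `ENTR` (Shannon entropy of the >= `lmin` length distribution, nats). An
#' all-zero matrix yields RR = 0 and all indices 0 by convention.
#'
#' @param mat binary matrix from [cross_recurrence_matrix()].
#' @param lmin minimal line length counted as deterministic (default 2).
#' @return object of class `eeg_cra` (a list of the five indices plus the
#'   line histogram and parameters).
#' @export
cra_indices <- function(mat, lmin = 2) {
  if (length(mat) == 0) stop("empty recurrence matrix")
  na <- nrow(mat); nb <- ncol(mat)
  diags <- split(mat, row(mat) - col(mat))
  hist <- integer(0)
  mdl <- 0L
  for (v in diags) {
    r <- rle(as.integer(v))
    runs <- r$lengths[r$values == 1L]
    if (length(runs)) {
      mx <- max(runs)
      if (mx > length(hist)) hist <- c(hist, integer(mx - length(hist)))
      tab <- tabulate(runs, nbins = length(hist))
      hist <- hist + tab
      mdl <- max(mdl, mx)
    }
  }
  lens <- seq_along(hist)
  pts_all <- sum(lens * hist)
  sel <- lens >= lmin
  pts_lmin <- sum(lens[sel] * hist[sel])
  nlines <- sum(hist[sel])
  p <- if (nlines > 0) hist[sel][hist[sel] > 0] / nlines else numeric(0)
  structure(
    list(RR = mean(mat),
         DET = if (pts_all > 0) pts_lmin / pts_all else 0,
         L = if (nlines > 0) pts_lmin / nlines else 0,
         MDL = as.numeric(mdl),
         ENTR = if (nlines > 0) -sum(p * log(p)) else 0,
         line_histogram = hist,
         params = list(lmin = lmin, eps = attr(mat, "eps"))),
    class = "eeg_cra"
  )
}

#' @export
print.eeg_cra <- function(x, ...) {
  cat(sprintf("<eeg_cra> RR=%.3f DET=%.3f L=%.2f MDL=%g ENTR=%.3f\n",
              x$RR, x$DET, x$L, x$MDL, x$ENTR))
  invisible(x)
}

#' Fast cross-recurrence indices from two trajectories
#'
#' Equivalent to `cra_indices(cross_recurrence_matrix(trajA, trajB, ...))`
#' but streams the distance computation in compiled code without
#' materialising the matrix.
#'
#' @inheritParams cross_recurrence_matrix
#' @param lmin minimal counted diagonal length.
#' @return object of class `eeg_cra`.
#' @export
cra_scan <- function(trajA, trajB, eps = NULL, rr_target = 0.1, lmin = 2) {
  trajA <- as.matrix(trajA); trajB <- as.matrix(trajB)
  res <- .cra_scan_cpp(trajA, trajB,
                       eps = if (is.null(eps)) 0 else eps,
                       rr_target = rr_target,
                       fixed_eps = !is.null(eps), lmin = as.integer(lmin))
  structure(
    list(RR = res$RR, DET = res$DET, L = res$L, MDL = res$MDL,
         ENTR = res$ENTR, line_histogram = res$line_histogram,
         params = list(lmin = lmin, eps = res$eps, rr_target = rr_target)),
    class = "eeg_cra"
  )
}

#' Band-limited cross-recurrence indices for a channel pair
#'
#' The two channels are band-pass filtered (zero phase), decimated to the
#' analysis rate, z-scored, delay-embedded (delay from the autocorrelation
#' minimum, dimension from false nearest neighbours, estimated on the first
#' window), and the CRA indices are computed per non-overlapping window and
#' averaged. MDL is reported in samples at the analysis rate.
#'
#' @param x,y the two channels (equal length).
#' @param sampling_interval_s seconds per sample of `x`/`y`.
#' @param band a [band()], band name, or `c(f_lo, f_hi)`.
#' @param index_name one of `"RR"`, `"DET"`, `"L"`, `"MDL"`, `"ENTR"`, or
#'   `"all"` (default) for the full set.
#' @param analysis_hz decimation target rate (default 25 Hz).
#' @param window_s analysis window (default 100 s).
#' @param rr_target fixed recurrence rate for the epsilon policy.
#' @param lmin minimal diagonal length.
#' @param m_max cap on the embedding dimension.
#' @return scalar (named index) or a one-row data.frame of all five indices
#'   with the embedding parameters.
#' @export
cra_band_index <- function(x, y, sampling_interval_s, band,
                           index_name = "all", analysis_hz = 25,
                           window_s = 100, rr_target = 0.1, lmin = 2,
                           m_max = 6) {
  b <- as_band(band)
  if (length(x) != length(y)) stop("channels must have the same length")
  dt <- sampling_interval_s
  xb <- decimate_to(bandpass(x, dt, b$f_lo, b$f_hi), dt, analysis_hz)
  yb <- decimate_to(bandpass(y, dt, b$f_lo, b$f_hi), dt, analysis_hz)
  xb <- (xb - mean(xb)) / sd(xb)
  yb <- (yb - mean(yb)) / sd(yb)
  adt <- 1 / analysis_hz
  nwin <- as.integer(round(window_s / adt))
  if (length(xb) < nwin) stop("record shorter than one CRA window")
  tau <- autocorr_delay(xb[seq_len(nwin)],
                        max_lag = min(as.integer(nwin / 2) - 1L,
                                      max(4L, as.integer(4 * analysis_hz))))
  # the FNN fraction stabilises well below a full window of samples
  nfnn <- min(nwin, max(1000L, (m_max + 1L) * tau + 200L))
  m <- as.integer(fnn_dimension(xb[seq_len(nfnn)], tau, m_max = m_max))
  starts <- seq(1L, length(xb) - nwin + 1L, by = nwin)
  res <- lapply(starts, function(s) {
    ta <- delay_embed(xb[s:(s + nwin - 1L)], m, tau)
    tb <- delay_embed(yb[s:(s + nwin - 1L)], m, tau)
    cra_scan(ta, tb, rr_target = rr_target, lmin = lmin)
  })
  avg <- function(nm) mean(vapply(res, `[[`, 0, nm))
  out <- data.frame(RR = avg("RR"), DET = avg("DET"), L = avg("L"),
                    MDL = avg("MDL"), ENTR = avg("ENTR"),
                    tau = tau, m = m, windows = length(res),
                    analysis_hz = analysis_hz)
  if (identical(index_name, "all")) return(out)
  if (!index_name %in% c("RR", "DET", "L", "MDL", "ENTR")) {
    stop("unknown index: ", index_name)
  }
  out[[index_name]]
}
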