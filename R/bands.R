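#' Frequency band definition
#'
#' A named frequency interval in Hz. The default band set follows the rodent
#' EEG conventions used throughout the package: the analysis theta band is
#' 4--8 Hz, the wide delta band 0--4 Hz, the "slow" delta band 0.1--0.5 Hz
#' (where the 0.1-Hz activity characteristic of blood--brain-barrier opening
#' lives), and the staging bands 5--10 Hz (theta) and 8--12 Hz (alpha-like
#' high-frequency activity).
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @return an object of class `eeg_band`.
#' @export
#' @examples
#' band("theta", 4, 8)
band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo >= 0 && f_hi > f_lo)) {
    stop("invalid band edges: need 0 <= f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "eeg_band")
}

#' @export
print.eeg_band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Default band set
#'
#' @return named list of [band()] objects.
#' @export
default_bands <- function() {
  list(
    delta_wide    = band("delta_wide", 0, 4),
    delta_slow    = band("delta_slow", 0.1, 0.5),
    theta         = band("theta", 4, 8),
    theta_staging = band("theta_staging", 5, 10),
    alpha         = band("alpha", 8, 12)
  )
}

as_band <- function(x) {
  if (inherits(x, "eeg_band")) return(x)
  if (is.character(x) && length(x) == 1L) {
    b <- default_bands()[[x]]
    if (is.null(b)) stop("unknown band name: ", x)
    return(b)
  }
  if (is.numeric(x) && length(x) == 2L) return(band("band", x[1], x[2]))
  stop("cannot interpret band specification")
}
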