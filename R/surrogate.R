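# AAFT surrogate-data significance testing, Mann-Whitney-Wilcoxon group
# contrasts, and mean +- SEM summaries.
#
# The amplitude-adjusted Fourier transform surrogate preserves a signal's
# amplitude distribution exactly (the surrogate is a permutation of the
# original values) and its periodogram approximately, while randomising the
# Fourier phases - destroying any nonlinear/phase structure. Comparing a
# coupling statistic on the original pair against its distribution over
# surrogates tests the hypothesis that the channels are not (linearly)
# coupled.

phase_randomize <- function(x) {
  n <- length(x)
  f <- fft(x)
  nh <- n %/% 2
  # random phases for bins 2..(ceiling(n/2)); DC (and Nyquist if even) real
  k <- if (n %% 2 == 0) nh - 1L else nh
  ph <- runif(k, 0, 2 * pi)
  rot <- rep(1 + 0i, n)
  rot[2:(k + 1L)] <- exp(1i * ph)
  rot[n:(n - k + 1L)] <- Conj(rot[2:(k + 1L)])
  Re(fft(f * rot, inverse = TRUE) / n)
}

#' Amplitude-adjusted Fourier transform (AAFT) surrogate
#'
#' Theiler's AAFT: rank-remap the signal to a Gaussian, randomise the Fourier
#' phases, and rank-remap back onto the original amplitude distribution. The
#' sorted surrogate values equal the sorted original values exactly.
#'
#' @param x numeric signal (length >= 32).
#' @param seed integer seed.
#' @return surrogate signal of the same length.
#' @export
aaft_surrogate <- function(x, seed) {
  n <- length(x)
  if (n < 32) stop("signal too short for a meaningful surrogate (need >= 32)")
  if (sd(x) == 0) stop("degenerate input: constant signal")
  with_seed(seed, {
    g <- sort(rnorm(n))[rank(x, ties.method = "first")]
    gp <- phase_randomize(g)
    sort(x)[rank(gp, ties.method = "first")]
  })
}

#' Surrogate-data significance test for a coupling statistic
#'
#' Compares `statistic_fn(x, y)` with its distribution over
#' `statistic_fn(x, surrogate(y))` for `n_surr` independently seeded AAFT
#' surrogates. One-sided p-value `(1 + #\{surrogate >= observed\}) /
#' (n_surr + 1)` (coupling statistics are one-directional; the convention
#' avoids p = 0).
#'
#' @param statistic_fn function of two signals returning a scalar.
#' @param x,y the signal pair.
#' @param n_surr number of surrogates (>= 19 for alpha = 0.05 resolution).
#' @param seed integer seed.
#' @param alpha significance level for the decision flag (0.05).
#' @return object of class `eeg_surrogate_test`: `observed`,
#'   `surrogate_stats`, `p_value`, `significant`.
#' @export
surrogate_test <- function(statistic_fn, x, y, n_surr = 99, seed = 1,
                           alpha = 0.05) {
  if (n_surr < 19) stop("need n_surr >= 19 for alpha = 0.05 resolution")
  observed <- statistic_fn(x, y)
  surr <- vapply(seq_len(n_surr), function(i) {
    ys <- aaft_surrogate(y, seed = mix_seed(seed, i))
    tryCatch(statistic_fn(x, ys),
             error = function(e) stop("statistic failed on surrogate ", i, ": ",
                                      conditionMessage(e)))
  }, numeric(1))
  p <- (1 + sum(surr >= observed)) / (n_surr + 1)
  structure(
    list(observed = observed, surrogate_stats = surr, n_surr = n_surr,
         p_value = p, alpha = alpha, significant = p < alpha),
    class = "eeg_surrogate_test"
  )
}

#' @export
print.eeg_surrogate_test <- function(x, ...) {
  cat(sprintf("<surrogate test> observed %.4g vs %d surrogates: p = %.4g%s\n",
              x$observed, x$n_surr, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Mann-Whitney-Wilcoxon two-sided group test
#'
#' Exact two-sided p-value for small groups (both n <= 8, no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors (each >= 3 values).
#' @return the two-sided p-value.
#' @export
mww_test <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 values")
  }
  if (length(unique(c(group_a, group_b))) == 1L) return(1)  # all tied
  exact <- length(group_a) <= 8 && length(group_b) <= 8 &&
    !any(duplicated(c(group_a, group_b)))
  p <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value
  )
  if (is.nan(p)) 1 else p
}

#' Group means with standard errors
#'
#' @param values_by_group named list of numeric vectors (each >= 2 values).
#' @return data.frame with `group`, `n`, `mean`, `sem` (= sd / sqrt(n)).
#' @export
group_summary <- function(values_by_group) {
  if (length(values_by_group) == 0) stop("no groups given")
  out <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    if (length(v) < 2) stop("group '", g, "' has fewer than 2 values")
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)))
  })
  do.call(rbind, out)
}
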