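# SNR feature extraction and the multilayer-perceptron similarity detector
# with the Cs statistic.
#
# The feature is the windowed signal-to-noise ratio SNR = E(X) / sigma(X)
# (sample mean over sample standard deviation, n-1 denominator) computed in
# 60-s windows advanced in 1-s steps. Consecutive runs of 90 SNR values (1.5
# min of steps) form one network input fragment. The network is the published
# architecture: 90 linear inputs, four sigmoid hidden layers of 500, 50, 500
# and 50 neurons, one linear output bounded to [0, 1]. Cs is the fraction of
# fragments the trained network scores above the similarity threshold.

#' Windowed signal-to-noise-ratio series
#'
#' @param x numeric signal.
#' @param sampling_interval_s seconds per sample.
#' @param window_s window length in seconds (default 60; at the native
#'   0.0005-s step this is 120,000 samples per window).
#' @param step_s window advance (default 1 s).
#' @return object of class `eeg_snr`: `values`, `window_s`, `step_s`.
#' @export
snr_series <- function(x, sampling_interval_s, window_s = 60, step_s = 1) {
  dt <- sampling_interval_s
  nw <- as.integer(round(window_s / dt))
  ns <- as.integer(round(step_s / dt))
  if (length(x) < nw) stop("signal shorter than one SNR window")
  starts <- seq(1L, length(x) - nw + 1L, by = ns)
  cs1 <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  s1 <- cs1[starts + nw] - cs1[starts]
  s2 <- cs2[starts + nw] - cs2[starts]
  mu <- s1 / nw
  v <- pmax(0, (s2 - nw * mu^2) / (nw - 1))
  if (any(v == 0)) {
    stop("zero-variance window at index ", which(v == 0)[1],
         ": SNR is undefined there")
  }
  structure(list(values = mu / sqrt(v), window_s = window_s, step_s = step_s),
            class = "eeg_snr")
}

#' @export
print.eeg_snr <- function(x, ...) {
  cat(sprintf("<eeg_snr> %d values, %g-s windows at %g-s steps\n",
              length(x$values), x$window_s, x$step_s))
  invisible(x)
}

#' Fragment an SNR series into network input vectors
#'
#' @param snr an `eeg_snr` (or plain numeric vector of SNR values).
#' @param fragment_len values per fragment (default 90, i.e. 1.5 min of 1-s
#'   steps).
#' @param stride step between fragment starts (default `fragment_len`:
#'   non-overlapping, keeping test fragments independent).
#' @return numeric matrix, one fragment per row.
#' @export
fragment_features <- function(snr, fragment_len = 90, stride = fragment_len) {
  v <- if (inherits(snr, "eeg_snr")) snr$values else as.numeric(snr)
  if (length(v) < fragment_len) {
    stop("need at least ", fragment_len, " SNR values (got ", length(v), ")")
  }
  starts <- seq(1L, length(v) - fragment_len + 1L, by = stride)
  t(vapply(starts, function(s) v[s:(s + fragment_len - 1L)],
           numeric(fragment_len)))
}

# --- multilayer perceptron ---------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(layers, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(layers) - 1L)) {
      lim <- sqrt(6 / (layers[l] + layers[l + 1L]))
      W[[l]] <- matrix(runif(layers[l] * layers[l + 1L], -lim, lim),
                       layers[l], layers[l + 1L])
      b[[l]] <- rep(0, layers[l + 1L])
    }
    list(W = W, b = b, layers = layers)
  })
}

# forward pass; returns activations per layer (hidden sigmoid, output linear)
mlp_forward <- function(model, X) {
  a <- list(X)
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    z <- sweep(a[[l]] %*% model$W[[l]], 2, model$b[[l]], `+`)
    a[[l + 1L]] <- if (l < nl) sigmoid(z) else z
  }
  a
}

#' Train the similarity detector
#'
#' Supervised training of the 90-500-50-500-50-1 perceptron: positive
#' fragments (the stimulated / OBBB-like state) target 1, negative fragments
#' target 0. Training minimises binary cross-entropy through a sigmoid on the
#' output unit (full-batch Adam); at inference the output is linear, hard
#' clamped to the unit interval. Inputs are standardised with the training set's
#' mean/sd (stored in the model). Deterministic given `seed`.
#'
#' @param positive_fragments,negative_fragments fragment matrices from
#'   [fragment_features()], at least 10 rows each.
#' @param hyperparams list; recognised entries `epochs` (200), `lr` (1e-3),
#'   `hidden` (c(500, 50, 500, 50)), `patience` (25), `tol` (1e-5).
#' @param seed integer seed for the weight initialisation.
#' @return object of class `eeg_mlp` with the weights, the input scaling and
#'   the training loss curve.
#' @export
train_detector <- function(positive_fragments, negative_fragments,
                           hyperparams = list(), seed = 1) {
  hp <- utils::modifyList(list(epochs = 200, lr = 1e-3,
                               hidden = c(500, 50, 500, 50),
                               patience = 25, tol = 1e-5), hyperparams)
  pos <- as.matrix(positive_fragments); neg <- as.matrix(negative_fragments)
  if (nrow(pos) < 10 || nrow(neg) < 10) {
    stop("need at least 10 fragments per class (got ", nrow(pos), " / ",
         nrow(neg), ")")
  }
  if (ncol(pos) != ncol(neg)) stop("fragment lengths differ between classes")
  X <- rbind(pos, neg)
  yv <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  layers <- c(ncol(X), hp$hidden, 1L)
  model <- mlp_init(layers, seed)
  nl <- length(model$W)
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  n <- nrow(Xs)
  loss <- numeric(0)
  best <- Inf; wait <- 0L
  for (ep in seq_len(hp$epochs)) {
    a <- mlp_forward(model, Xs)
    p <- sigmoid(a[[nl + 1L]][, 1])
    loss[ep] <- -mean(yv * log(pmax(p, 1e-12)) +
                        (1 - yv) * log(pmax(1 - p, 1e-12)))
    delta <- matrix((p - yv) / n, ncol = 1)          # dL/dz_out
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(model$W[[l]])) * a[[l]] * (1 - a[[l]])
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
      model$W[[l]] <- model$W[[l]] -
        hp$lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + epsa)
      model$b[[l]] <- model$b[[l]] -
        hp$lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + epsa)
    }
    if (loss[ep] < best - hp$tol) { best <- loss[ep]; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= hp$patience) break }
  }
  structure(
    list(W = model$W, b = model$b, layers = layers, center = ctr, scale = scl,
         loss_curve = loss, epochs_run = length(loss), seed = seed),
    class = "eeg_mlp"
  )
}

#' @export
print.eeg_mlp <- function(x, ...) {
  cat(sprintf("<eeg_mlp> layers %s, %d epoch(s), final loss %.4g\n",
              paste(x$layers, collapse = "-"), x$epochs_run,
              tail(x$loss_curve, 1)))
  invisible(x)
}

#' Network response to fragments
#'
#' Forward pass with the linear output hard-clamped to `[0, 1]`
#' (1 = maximal similarity to the positive training class).
#'
#' @param model an `eeg_mlp` from [train_detector()].
#' @param fragment one fragment (length-90 vector) or a fragment matrix.
#' @return numeric vector of responses in `[0, 1]`.
#' @export
network_response <- function(model, fragment) {
  X <- if (is.matrix(fragment)) fragment else matrix(fragment, nrow = 1)
  if (ncol(X) != model$layers[1]) {
    stop("fragment length ", ncol(X), " does not match the network input size ",
         model$layers[1])
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  z <- mlp_forward(model, Xs)[[length(model$W) + 1L]][, 1]
  pmin(1, pmax(0, z))
}

#' Cs: fraction of fragments recognised as similar
#'
#' `Cs = #\{responses > threshold\} / #responses`, the part of EEG fragments
#' the network recognises as similar to its positive training fragments.
#' (The alternative literal similar/dissimilar count ratio, which can exceed
#' 1, is available via [cs_count_ratio()].)
#'
#' @param responses numeric responses from [network_response()].
#' @param threshold similarity threshold (default 0.5).
#' @return Cs in `[0, 1]`.
#' @export
compute_cs <- function(responses, threshold = 0.5) {
  if (length(responses) == 0) stop("no responses given")
  mean(responses > threshold)
}

#' Literal similar/dissimilar count ratio
#'
#' `sum(N_i^s) / sum(N_i^d)` over subjects: the printed alternative form of
#' the similarity statistic. Unlike [compute_cs()] this is not a fraction of
#' the total and can exceed 1 (it is `Inf` when nothing is dissimilar).
#'
#' @param responses numeric responses.
#' @param threshold similarity threshold (default 0.5).
#' @return non-negative ratio (possibly `Inf`).
#' @export
cs_count_ratio <- function(responses, threshold = 0.5) {
  if (length(responses) == 0) stop("no responses given")
  ns <- sum(responses > threshold)
  nd <- sum(responses <= threshold)
  if (nd == 0) Inf else ns / nd
}

#' Leave-one-subject training protocol
#'
#' For each subject in turn, a detector is trained on that subject's positive
#' (OBBB-like) versus negative (wake) fragments and evaluated on all *other*
#' subjects' fragments state by state; per-state Cs values are then summarised
#' over the trained networks (mean and SEM). Subjects lacking 10 fragments in
#' either training class are skipped with a warning.
#'
#' @param fragments nested list: `fragments[[subject]][[state]]` is a fragment
#'   matrix (rows = fragments) for that subject and state; used for
#'   evaluation (non-overlapping fragments keep the per-network Cs values
#'   comparable).
#' @param train_fragments optional nested list of the same shape used for
#'   training only (e.g. cut with a denser stride to enlarge the training
#'   set); defaults to `fragments`.
#' @param positive_state,negative_state names of the training states
#'   (defaults `"obbb"` / `"wake"`).
#' @param hyperparams passed to [train_detector()].
#' @param threshold similarity threshold for Cs.
#' @param seed master seed (one derived seed per trained network).
#' @return list with `per_network` (data.frame: training subject, state, Cs)
#'   and `summary` (data.frame: state, mean Cs, SEM, n networks).
#' @export
leave_one_subject_protocol <- function(fragments, positive_state = "obbb",
                                       negative_state = "wake",
                                       hyperparams = list(), threshold = 0.5,
                                       seed = 1, train_fragments = NULL) {
  subjects <- names(fragments)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  train_fragments <- train_fragments %||% fragments
  rows <- list()
  k <- 0L
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    pos <- train_fragments[[sub]][[positive_state]]
    neg <- train_fragments[[sub]][[negative_state]]
    if (is.null(pos) || is.null(neg) || nrow(pos) < 10 || nrow(neg) < 10) {
      warning("subject ", sub, " lacks 10 fragments in both training classes; skipped")
      next
    }
    model <- train_detector(pos, neg, hyperparams, seed = mix_seed(seed, si))
    for (other in subjects[-si]) {
      for (state in names(fragments[[other]])) {
        fr <- fragments[[other]][[state]]
        if (is.null(fr) || nrow(fr) == 0) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          train_subject = sub, state = state,
          cs = compute_cs(network_response(model, fr), threshold),
          n_fragments = nrow(fr))
      }
    }
  }
  if (k == 0L) stop("no subject had both training classes")
  per <- do.call(rbind, rows)
  # per-network Cs per state (pool fragments over evaluated subjects equally
  # weighted by fragment count)
  agg <- stats::aggregate(cbind(w = cs * n_fragments, n_fragments) ~
                            train_subject + state, data = per, FUN = sum)
  agg$cs <- agg$w / agg$n_fragments
  summ <- do.call(rbind, lapply(split(agg, agg$state), function(d) {
    data.frame(state = d$state[1], mean_cs = mean(d$cs),
               sem_cs = sd(d$cs) / sqrt(nrow(d)), n_networks = nrow(d))
  }))
  rownames(summ) <- NULL
  list(per_network = agg[, c("train_subject", "state", "cs")], summary = summ)
}
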