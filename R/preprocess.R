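# Zero-phase filtering with odd-symmetric edge padding (scipy-style):
# the signal is extended at both ends by its point-reflection, filtered
# forward and backward, and the extensions dropped. Keeps constants exact
# and suppresses startup transients on short epochs.
filtfilt_padded <- function(b, a, x, pad = NULL) {
  b <- as.numeric(b)
  a <- as.numeric(a)
  n <- length(x)
  if (is.null(pad)) pad <- 3L * (max(length(a), length(b)) - 1L) + 12L
  pad <- min(n - 1L, pad)
  if (pad > 0) {
    # even (mirror) reflection: value-continuous at the junctions and free
    # of the DC offset an odd reflection would inject into a notch filter
    xe <- c(x[seq(pad + 1, 2)], x, x[seq(n - 1, n - pad)])
  } else xe <- x
  # steady-state-at-the-edge initial conditions (both filters have DC
  # gain 1), so a constant signal passes through exactly
  run <- function(z) signal::filter(b, a, z,
                                    init.x = rep(z[1], length(b) - 1L),
                                    init.y = rep(z[1], length(a) - 1L))
  y <- run(xe)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Notch filter for power-line interference
#'
#' Zero-phase removal of a narrow band around `f0_hz`. Below the Nyquist
#' frequency a second-order IIR notch (unit-circle zeros at `f0_hz`, DC and
#' Nyquist gain 1) is applied forward and backward, giving > 40 dB
#' rejection at `f0_hz` and phase distortion cancelled. When `f0_hz`
#' equals the Nyquist frequency exactly (e.g. a 50 Hz notch on a 100 Hz
#' recording) the IIR design degenerates, so a zero-phase windowed-sinc
#' FIR low-pass with cutoff just below Nyquist is substituted — it has a
#' zero at Nyquist and a flat passband — and a warning is emitted.
#'
#' @param samples Numeric vector or matrix (rows = time, columns =
#'   channels).
#' @param fs_hz Sampling rate in Hz.
#' @param f0_hz Notch frequency in Hz; must satisfy `0 < f0_hz <= fs_hz/2`.
#' @param q Quality factor of the IIR notch (centre frequency / -3 dB
#'   bandwidth); higher = narrower.
#' @return Filtered samples, same shape and length as the input.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1e-3))
#' y <- notch_filter(x, fs_hz = 1000, f0_hz = 50)
notch_filter <- function(samples, fs_hz, f0_hz = 50, q = 30) {
  if (f0_hz <= 0 || f0_hz > fs_hz / 2)
    stop("`f0_hz` must satisfy 0 < f0_hz <= fs_hz/2", call. = FALSE)
  at_nyquist <- isTRUE(all.equal(f0_hz, fs_hz / 2))
  if (at_nyquist) {
    warning("notch frequency equals the Nyquist frequency (", fs_hz / 2,
            " Hz); substituting a zero-phase FIR low-pass with a zero at ",
            "Nyquist", call. = FALSE)
    b <- as.numeric(signal::fir1(30, 0.9, type = "low"))
    b <- b / sum(b)  # exact unit DC gain
    a <- 1
    pad <- NULL
  } else {
    # biquad notch: zeros on the unit circle at +/- w0, poles just inside
    w0 <- 2 * pi * f0_hz / fs_hz
    alpha <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    # pad past the resonant ring-down so edge transients cannot reach
    # the retained samples
    r <- sqrt((1 - alpha) / (1 + alpha))
    pad <- ceiling(6 / (1 - r))
  }
  apply_cols <- function(m) {
    out <- m
    for (ch in seq_len(ncol(m)))
      out[, ch] <- filtfilt_padded(b, a, m[, ch], pad = pad)
    out
  }
  if (is.matrix(samples)) apply_cols(samples)
  else as.numeric(filtfilt_padded(b, a, samples, pad = pad))
}

#' Segment concatenated signals into sliding analysis windows
#'
#' Cuts each class's concatenated signal into fixed-length windows moved
#' forward by a fixed increment: with signal length L, window length W and
#' increment I (all in samples), window starts are 0, I, 2I, ... and the
#' window count per class is floor((L - W) / I) + 1. Each window is
#' labelled with its class and attributed to the repetition containing its
#' first sample; with `straddle = FALSE`, windows spanning a repetition
#' boundary are dropped, so no window mixes samples from two repetitions.
#'
#' @param concat An `rsc_concat` from [concatenate_recordings()].
#' @param window_ms Window length in milliseconds (default 300).
#' @param increment_ms Window increment in milliseconds (default 100);
#'   must satisfy `window_ms >= increment_ms > 0`.
#' @param straddle Allow windows to straddle repetition boundaries
#'   (default TRUE, the concatenate-then-window procedure); FALSE gives
#'   strictly leak-free windows for cross-validation.
#' @return An `rsc_windows` dataset: a `windows` array of dimension
#'   (n_windows, window_len, n_channels), per-window class `labels` and
#'   `rep_of_window`, and the segmentation parameters.
#' @export
segment_windows <- function(concat, window_ms = 300, increment_ms = 100,
                            straddle = TRUE) {
  stopifnot(inherits(concat, "rsc_concat"))
  if (increment_ms <= 0 || window_ms < increment_ms)
    stop("need window_ms >= increment_ms > 0", call. = FALSE)
  fs <- concat$fs_hz
  W <- as.integer(round(window_ms * fs / 1000))
  I <- as.integer(round(increment_ms * fs / 1000))
  if (W < 2) stop("window too short: ", W, " sample(s)", call. = FALSE)
  per_class <- lapply(names(concat$classes), function(cl) {
    set <- concat$classes[[cl]]
    L <- nrow(set$samples)
    if (L < W)
      stop("class `", cl, "` signal (", L,
           " samples) is shorter than one window (", W, ")", call. = FALSE)
    starts <- seq.int(0L, L - W, by = I)
    reps <- set$rep_index[findInterval(starts, set$boundaries)]
    if (!straddle) {
      rep_last <- set$rep_index[findInterval(starts + W - 1L,
                                             set$boundaries)]
      keep <- reps == rep_last
      starts <- starts[keep]
      reps <- reps[keep]
    }
    list(class = cl, starts = starts, reps = reps, samples = set$samples)
  })
  n_total <- sum(vapply(per_class, function(p) length(p$starts), integer(1)))
  n_ch <- length(concat$channel_ids)
  windows <- array(0, dim = c(n_total, W, n_ch))
  labels <- character(n_total)
  rep_of_window <- integer(n_total)
  i <- 0L
  for (p in per_class) {
    for (k in seq_along(p$starts)) {
      i <- i + 1L
      windows[i, , ] <- p$samples[(p$starts[k] + 1L):(p$starts[k] + W), ,
                                  drop = FALSE]
      labels[i] <- p$class
      rep_of_window[i] <- p$reps[k]
    }
  }
  structure(list(windows = windows,
                 labels = factor(labels, levels = names(concat$classes)),
                 rep_of_window = rep_of_window,
                 window_len_samples = W, increment_samples = I,
                 window_ms = window_ms, increment_ms = increment_ms,
                 fs_hz = fs, channel_ids = concat$channel_ids),
            class = "rsc_windows")
}

#' @export
print.rsc_windows <- function(x, ...) {
  cat(sprintf("Windowed RSC dataset: %d windows of %d samples (%g ms), %s\n",
              dim(x$windows)[1], x$window_len_samples, x$window_ms,
              paste0("increment ", x$increment_samples, " samples")))
  print(table(x$labels))
  invisible(x)
}

#' Contaminate a signal with white Gaussian noise
#'
#' Adds, per channel, i.i.d. Gaussian noise whose standard deviation is
#' `ratio_pct`% of that channel's RMS over the full signal (amplitude
#' interpretation of the noise ratio). `ratio_pct = 0` returns the input
#' unchanged; the draw is deterministic given `seed`.
#'
#' @param samples Numeric vector or matrix (rows = time, columns =
#'   channels).
#' @param ratio_pct Noise ratio in percent (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return Contaminated samples, same shape as the input.
#' @export
add_white_noise <- function(samples, ratio_pct, seed = 1) {
  if (!is.numeric(ratio_pct) || length(ratio_pct) != 1 || ratio_pct < 0)
    stop("`ratio_pct` must be a single value >= 0", call. = FALSE)
  if (ratio_pct == 0) return(samples)
  m <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  rms <- sqrt(colMeans(m^2))
  noise <- with_local_seed(seed, function() {
    matrix(rnorm(length(m)), nrow = nrow(m))
  })
  out <- m + sweep(noise, 2, (ratio_pct / 100) * rms, `*`)
  if (is.matrix(samples)) out else as.numeric(out)
}
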