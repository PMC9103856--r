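# Feature pipeline: band-pass conditioning, linear envelope, sliding RMS,
# Morse-wavelet scalogram, per-signal min-max normalization, and 10-sample
# sliding-window segmentation with majority labels.

#' Band-pass condition a raw sEMG signal (10-500 Hz)
#'
#' 2nd-order Butterworth band-pass, applied forward and backward so the
#' output is zero-phase. Requires `fs_hz > 1000` so the 500 Hz upper cut-off
#' stays below Nyquist.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling frequency, Hz.
#' @return Filtered signal, same length.
#' @export
bandpass_semg <- function(x, fs_hz = 2000) {
  if (fs_hz <= 1000) stop("fs_hz must exceed 1000 Hz (500 Hz upper cut-off)")
  bf <- signal::butter(2, c(10, 500) / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Linear envelope
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass at 5 Hz: the classical linear envelope of an sEMG signal. A
#' zero-mean signal low-passed at 5 Hz without rectification is close to
#' zero, so rectification is on by default but can be disabled.
#'
#' @param x Numeric signal (band-pass conditioned).
#' @param fs_hz Sampling frequency, Hz.
#' @param cutoff_hz Low-pass cut-off, Hz.
#' @param rectify Apply `abs()` before the low-pass (default `TRUE`).
#' @return Envelope, same length as `x`.
#' @export
linear_envelope <- function(x, fs_hz = 2000, cutoff_hz = 5, rectify = TRUE) {
  if (length(x) == 0) stop("empty signal")
  r <- if (rectify) abs(x) else x
  bf <- signal::butter(2, cutoff_hz / (fs_hz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, r))
}

#' Sliding-window RMS profile
#'
#' Per-sample root mean square over a centered window (default 60 samples,
#' i.e. 30 ms at 2000 Hz) with stride 1; edges are reflect-padded so the
#' output has the same length as the input.
#'
#' @param x Numeric signal.
#' @param window_samples Window length in samples.
#' @return RMS sequence, same length as `x`.
#' @export
rms_profile <- function(x, window_samples = 60) {
  n <- length(x)
  w <- as.integer(window_samples)
  stopifnot(w >= 1)
  if (w > n) stop("window_samples exceeds signal length")
  if (w == 1) return(abs(x))
  left <- (w - 1) %/% 2
  right <- w - 1 - left
  xp <- c(rev(x[seq_len(left) + 1]), x, rev(x[n - seq_len(right)]))
  cs <- cumsum(c(0, xp^2))
  sqrt(pmax((cs[seq_len(n) + w] - cs[seq_len(n)]) / w, 0))
}

#' Center frequencies of the scalogram scale set
#'
#' Log-spaced center frequencies (Hz) used by [cwt_scalogram()], spanning
#' `freq_range` with `n_scales` levels, ordered low to high.
#'
#' @param n_scales Number of scales.
#' @param freq_range Two-element range in Hz.
#' @return Numeric vector of length `n_scales`.
#' @export
morse_center_freqs <- function(n_scales = 6, freq_range = c(20, 500)) {
  stopifnot(n_scales >= 1, length(freq_range) == 2, all(freq_range > 0))
  if (n_scales == 1) return(sqrt(prod(freq_range)))
  exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_scales))
}

# Frequency-domain generalized Morse wavelet, psi_hat(w) = a * w^beta *
# exp(-w^gamma) for w > 0, normalized to peak value 2 at the peak frequency
# (beta/gamma)^(1/gamma). Analytic: zero at negative frequencies.
morse_wavelet_hat <- function(w, gamma = 3, beta = 4) {
  wp <- (beta / gamma)^(1 / gamma)
  out <- numeric(length(w))
  pos <- w > 0
  lw <- log(w[pos])
  out[pos] <- 2 * exp(beta * (lw - log(wp)) - w[pos]^gamma + wp^gamma)
  out
}

#' Continuous-wavelet-transform scalogram
#'
#' Squared magnitude of the continuous wavelet transform of `x` computed with
#' a generalized Morse mother wavelet (default symmetry `gamma = 3`, order
#' `beta = 4`) at `n_scales` log-spaced scales whose center frequencies span
#' `freq_range`. The transform is evaluated in the frequency domain via the
#' FFT; the wavelet is analytic, so each row is the squared modulus of a
#' complex band-pass response.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling frequency, Hz.
#' @param n_scales Number of decomposition levels (default 6).
#' @param gamma,beta Morse wavelet parameters.
#' @param freq_range Range of scale center frequencies, Hz.
#' @return `n_scales x length(x)` nonnegative matrix; rows ordered by
#'   increasing center frequency, recorded in attribute `center_freqs_hz`.
#' @export
cwt_scalogram <- function(x, fs_hz = 2000, n_scales = 6, gamma = 3, beta = 4,
                          freq_range = c(20, 500)) {
  n <- length(x)
  stopifnot(n >= 2, n_scales >= 1)
  freqs <- morse_center_freqs(n_scales, freq_range)
  wp <- (beta / gamma)^(1 / gamma)
  xh <- stats::fft(x)
  # radian frequency per sample for FFT bins; negative half set to zero by
  # the analytic wavelet
  w <- 2 * pi * (seq_len(n) - 1) / n
  w[w > pi] <- 0 # negative-frequency bins: wavelet support excludes them
  P <- matrix(0, nrow = n_scales, ncol = n)
  for (k in seq_len(n_scales)) {
    s <- wp * fs_hz / (2 * pi * freqs[k])
    Wk <- stats::fft(xh * morse_wavelet_hat(s * w, gamma, beta),
                     inverse = TRUE) / n
    P[k, ] <- Mod(Wk)^2
  }
  attr(P, "center_freqs_hz") <- freqs
  P
}

#' Min-max normalize a feature channel to [0, 1]
#'
#' `(x - min) / (max - min)` computed per channel within one signal. A
#' constant channel carries no information and maps to all zeros.
#'
#' @param x Numeric vector.
#' @return Vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  d <- r[2] - r[1]
  if (d == 0) return(numeric(length(x)))
  (x - r[1]) / d
}

#' Build the per-sample feature matrix of a signal
#'
#' Stacks the selected channels -- linear envelope (`"le"`), sliding RMS
#' (`"rms"`) and the rows of the Morse-wavelet scalogram (`"cwt"`) -- each
#' min-max normalized per signal, into an `n_samples x n_channels` matrix.
#' The default concatenation LE + RMS + CWT gives 8 channels; single-channel
#' ablations are selected via `channels`.
#'
#' @param x Numeric signal, already band-pass conditioned (see
#'   [bandpass_semg()]).
#' @param fs_hz Sampling frequency, Hz.
#' @param channels Subset of `c("le", "rms", "cwt")`.
#' @param n_scales Scalogram levels (default 6).
#' @param rms_window RMS window length, samples.
#' @param normalize Min-max normalize each channel (default `TRUE`).
#' @param ... Further arguments passed to [cwt_scalogram()].
#' @return Object of class `feature_matrix`: list with `channels` (matrix),
#'   `channel_names`, `fs_hz`, `normalized`.
#' @export
build_feature_matrix <- function(x, fs_hz = 2000,
                                 channels = c("le", "rms", "cwt"),
                                 n_scales = 6, rms_window = 60,
                                 normalize = TRUE, ...) {
  channels <- match.arg(channels, c("le", "rms", "cwt"), several.ok = TRUE)
  cols <- list()
  names_out <- character()
  if ("le" %in% channels) {
    cols <- c(cols, list(linear_envelope(x, fs_hz)))
    names_out <- c(names_out, "le")
  }
  if ("rms" %in% channels) {
    cols <- c(cols, list(rms_profile(x, rms_window)))
    names_out <- c(names_out, "rms")
  }
  if ("cwt" %in% channels) {
    P <- cwt_scalogram(x, fs_hz, n_scales = n_scales, ...)
    for (k in seq_len(nrow(P))) cols <- c(cols, list(P[k, ]))
    names_out <- c(names_out, paste0("cwt", seq_len(nrow(P))))
  }
  M <- do.call(cbind, cols)
  if (normalize) M <- apply(M, 2, minmax_normalize)
  colnames(M) <- names_out
  structure(list(channels = M, channel_names = names_out, fs_hz = fs_hz,
                 normalized = isTRUE(normalize)),
            class = "feature_matrix")
}

#' Segment a feature matrix into labeled sliding windows
#'
#' Cuts the per-sample feature matrix into overlapping windows of
#' `window_len` samples shifted by one sample. Each window is flattened
#' (channel-major) into one row and labels a single anchor sample (the
#' center-right sample, offset `window_len / 2`, giving a 3-4 ms latency at
#' 2000 Hz). The window label is the majority of the ground-truth values it
#' covers; 5/5 ties label 1 (activity).
#'
#' @param features A [build_feature_matrix()] object, or a plain numeric
#'   matrix `n_samples x n_channels`.
#' @param ground_truth Binary vector, one value per sample.
#' @param window_len Window length in samples (default 10).
#' @return Object of class `windowed_dataset`: list with `windows`
#'   (`n_windows x (window_len * n_channels)` matrix), `labels` (0/1
#'   integer), `anchor_index` (1-based sample index each window labels),
#'   `window_len`, `n_channels`, `fs_hz`.
#' @export
window_and_label <- function(features, ground_truth, window_len = 10) {
  M <- if (inherits(features, "feature_matrix")) features$channels else features
  fs <- if (inherits(features, "feature_matrix")) features$fs_hz else NA_real_
  stopifnot(is.matrix(M))
  n <- nrow(M)
  w <- as.integer(window_len)
  if (n < w) stop("signal shorter than one window")
  stopifnot(length(ground_truth) == n)
  nw <- n - w + 1
  nch <- ncol(M)
  X <- matrix(0, nrow = nw, ncol = w * nch)
  for (ch in seq_len(nch)) {
    for (k in seq_len(w)) {
      X[, (ch - 1) * w + k] <- M[k:(k + nw - 1), ch]
    }
  }
  cs <- cumsum(c(0, as.numeric(ground_truth)))
  ones <- cs[seq_len(nw) + w] - cs[seq_len(nw)]
  labels <- as.integer(2 * ones >= w) # ties (w/2 of each) label activity
  anchor <- seq_len(nw) + w %/% 2L
  structure(list(windows = X, labels = labels, anchor_index = anchor,
                 window_len = w, n_channels = nch, fs_hz = fs),
            class = "windowed_dataset")
}

#' Spread per-window predictions back onto samples
#'
#' Each window predicts its anchor sample; the `window_len / 2` samples
#' before the first anchor and after the last take the nearest window's
#' prediction, so the output covers every sample of the original signal.
#'
#' @param window_values Numeric or integer vector, one value per window.
#' @param anchor_index 1-based anchor sample of each window (from
#'   [window_and_label()]).
#' @param n_samples Length of the original signal.
#' @return Vector of length `n_samples`.
#' @export
windows_to_samples <- function(window_values, anchor_index, n_samples) {
  stopifnot(length(window_values) == length(anchor_index))
  out <- rep(window_values[1], n_samples)
  out[anchor_index] <- window_values
  last <- anchor_index[length(anchor_index)]
  if (last < n_samples) {
    out[(last + 1):n_samples] <- window_values[length(window_values)]
  }
  out
}
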