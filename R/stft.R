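#' Short-time Fourier transform of epoched trials
#'
#' Slides a tapered window across every trial and channel and returns
#' one-sided complex Fourier coefficients in bands spaced
#' `1000 / window_ms` Hz apart from 0 Hz to Nyquist. Coefficients are
#' demodulated to the window's centre sample — so the real part of a band's
#' coefficient tracks the narrowband signal value at that timepoint and the
#' imaginary part its quadrature (gradient) component — and scaled so a
#' unit-amplitude sinusoid at a band centre yields unit magnitude. The 0 Hz
#' band (and the Nyquist band, when the window length is even) has an
#' identically zero imaginary part. Epoch edges are handled by symmetric
#' reflection padding by default, so the output time axis spans the epoch;
#' `padding = "valid"` restricts to fully interior windows instead.
#'
#' @param dataset a `trial_dataset`.
#' @param window_ms window length in milliseconds (must fit in the epoch).
#' @param hop_samples hop between window centres, in samples (default 1:
#'   one coefficient per timepoint).
#' @param window_shape `"hamming"` (default), `"hann"`, or `"rectangular"`.
#' @param padding `"reflect"` (default) or `"valid"`.
#' @return a `spectral_features` object: `coeffs` (trials x channels x
#'   bands x time complex array), `band_hz`, `time_s`, `labels`, window
#'   metadata.
#' @export
stft_epochs <- function(dataset, window_ms = 100, hop_samples = 1,
                        window_shape = c("hamming", "hann", "rectangular"),
                        padding = c("reflect", "valid")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  window_shape <- match.arg(window_shape)
  padding <- match.arg(padding)
  fs <- dataset$sample_rate_hz
  Tn <- dim(dataset$data)[3]
  if (window_ms <= 0) stop("window_ms must be positive")
  L <- as.integer(round(window_ms / 1000 * fs))
  if (L < 2) stop("window shorter than two samples")
  if (L > Tn) stop("window longer than the epoch")
  if (hop_samples < 1) stop("hop_samples must be a positive integer")

  win <- .stft_window(window_shape, L)
  n_bands <- L %/% 2 + 1
  band_hz <- (seq_len(n_bands) - 1) * fs / L
  c0 <- L %/% 2  # demodulation reference: integer centre sample

  # complex projection matrix: L x bands, conj(win * e^{i 2 pi k (n - c0)/L})
  n_idx <- 0:(L - 1)
  Wmat <- sapply(seq_len(n_bands) - 1, function(k)
    win * exp(-1i * 2 * pi * k * (n_idx - c0) / L))
  scale <- ifelse(band_hz == 0 | (L %% 2 == 0 & band_hz == fs / 2),
                  1 / sum(win), 2 / sum(win))
  Wmat <- sweep(Wmat, 2, scale, "*")

  N <- dim(dataset$data)[1]
  P <- dim(dataset$data)[2]
  if (padding == "reflect") {
    pad_l <- c0
    pad_r <- L - 1 - c0
    centres <- seq(1, Tn, by = hop_samples)
  } else {
    pad_l <- 0
    pad_r <- 0
    centres <- seq(1 + c0, Tn - (L - 1 - c0), by = hop_samples)
    if (length(centres) == 0) stop("no fully interior window positions")
  }
  # flatten trials*channels into rows, pad along time
  D <- matrix(aperm(dataset$data, c(3, 1, 2)), nrow = Tn)  # Tn x (N*P)
  if (pad_l > 0 || pad_r > 0) {
    left <- D[rev(seq_len(pad_l) + 1), , drop = FALSE]
    right <- D[Tn - seq_len(pad_r), , drop = FALSE]
    D <- rbind(left, D, right)
  }
  coeffs <- array(0i, dim = c(N, P, n_bands, length(centres)))
  for (j in seq_along(centres)) {
    rows <- (centres[j] - c0 + pad_l) + n_idx  # window sample rows in D
    seg <- D[rows, , drop = FALSE]             # L x (N*P)
    cf <- crossprod(seg, Wmat)                 # (N*P) x bands
    coeffs[, , , j] <- array(cf, dim = c(N, P, n_bands))
  }
  # enforce the exact-zero imaginary invariant at DC and Nyquist
  coeffs[, , band_hz == 0, ] <- Re(coeffs[, , band_hz == 0, , drop = FALSE])
  if (L %% 2 == 0)
    coeffs[, , n_bands, ] <- Re(coeffs[, , n_bands, , drop = FALSE])

  structure(list(
    coeffs = coeffs,
    band_hz = band_hz,
    window_ms = window_ms,
    window_shape = window_shape,
    hop_samples = as.integer(hop_samples),
    padding = padding,
    sample_rate_hz = fs,
    time_s = dataset$time_s[centres],
    labels = dataset$labels
  ), class = "spectral_features")
}

# Periodic (DFT-even) tapers: their discrete spectrum is confined to bin
# offsets {0, +/-1}, so a sinusoid at a band centre produces an exactly
# unit-magnitude coefficient in its own band (the symmetric variants leak).
.stft_window <- function(shape, L) {
  n <- 0:(L - 1)
  switch(shape,
         hamming = 0.54 - 0.46 * cos(2 * pi * n / L),
         hann = 0.5 - 0.5 * cos(2 * pi * n / L),
         rectangular = rep(1, L))
}

#' @export
print.spectral_features <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<spectral_features> %d trials x %d channels x %d bands x %d timepoints\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  %s window %g ms, hop %d, bands %g..%g Hz (step %g Hz)\n",
              x$window_shape, x$window_ms, x$hop_samples,
              min(x$band_hz), max(x$band_hz), 1000 / x$window_ms))
  invisible(x)
}

.feature_band_index <- function(features, band_hz) {
  stopifnot(inherits(features, "spectral_features"))
  b <- which(abs(features$band_hz - band_hz) < 1e-9)
  if (length(b) != 1)
    stop(sprintf("band %g Hz not in the feature set (%s)", band_hz,
                 paste(features$band_hz, collapse = ", ")))
  b
}

#' Real (narrowband-signal) feature view of one band
#'
#' The real parts of one band's STFT coefficients: P features per
#' timepoint, equivalent to decoding a band-pass-filtered signal.
#'
#' @param features a `spectral_features` object.
#' @param band_hz a band centre frequency.
#' @return trials x channels x time numeric array.
#' @export
band_real_features <- function(features, band_hz) {
  b <- .feature_band_index(features, band_hz)
  d <- dim(features$coeffs)
  array(Re(features$coeffs[, , b, ]), dim = d[c(1, 2, 4)])
}

#' Complex (real + imaginary) feature view of one band
#'
#' Real and imaginary coefficient parts stacked channel-wise: 2P features
#' per timepoint, capturing both the instantaneous narrowband value and
#' its gradient. The first P features equal [band_real_features()].
#'
#' @inheritParams band_real_features
#' @return trials x (2 * channels) x time numeric array.
#' @export
band_complex_features <- function(features, band_hz) {
  b <- .feature_band_index(features, band_hz)
  d <- dim(features$coeffs)
  out <- array(0, dim = c(d[1], 2 * d[2], d[4]))
  out[, seq_len(d[2]), ] <- Re(features$coeffs[, , b, ])
  out[, d[2] + seq_len(d[2]), ] <- Im(features$coeffs[, , b, ])
  out
}
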