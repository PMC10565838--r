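#' Information bandwidth of a model
#'
#' The squared class separation — and hence any decoding-accuracy or
#' mutual-information timecourse — contains harmonics up to twice the
#' highest evoked component frequency. Returns `2 * Omega`, with `Omega`
#' the highest frequency carrying nonzero amplitude on any channel.
#'
#' @param model an [evoked_spectrum_model()].
#' @return information bandwidth in Hz.
#' @export
info_bandwidth <- function(model) {
  stopifnot(inherits(model, "evoked_spectrum_model"))
  nz <- apply(model$amplitudes, 1, function(a) any(a > 0))
  if (!any(nz)) stop("all amplitudes are zero: no information spectrum")
  2 * max(model$freqs_hz[nz])
}

#' Fold a frequency about the Nyquist limit
#'
#' Maps a frequency into the observable range `[0, Fs/2]` of a signal
#' sampled at `sample_rate_hz`, by reflection about multiples of the
#' Nyquist frequency: `f mod Fs`, reflected to `Fs - (f mod Fs)` when above
#' `Fs/2`. Identity for frequencies at or below Nyquist; idempotent on its
#' own output and periodic in `freq_hz` with period `Fs`.
#'
#' @param freq_hz non-negative frequency (vectorised).
#' @param sample_rate_hz positive sampling rate.
#' @return the observed (folded) frequency in `[0, Fs/2]`.
#' @export
alias_frequency <- function(freq_hz, sample_rate_hz) {
  if (any(sample_rate_hz <= 0)) stop("sample rate must be positive")
  if (any(freq_hz < 0)) stop("frequency must be non-negative")
  r <- freq_hz %% sample_rate_hz
  ifelse(r > sample_rate_hz / 2, sample_rate_hz - r, r)
}

#' Minimum alias-free sampling rate for instantaneous decoding
#'
#' Information timecourses occupy frequencies up to `2 * Omega`, so the
#' sampled accuracy timecourse is alias-free only when the Nyquist
#' frequency is at least `2 * Omega`, i.e. `Fs >= 4 * Omega` — the signal
#' content must be kept below one quarter of the sampling rate.
#'
#' @param model an [evoked_spectrum_model()].
#' @return minimum sampling rate in Hz (`4 * Omega`).
#' @export
min_sample_rate <- function(model) {
  2 * info_bandwidth(model)
}

#' Per-band representational-aliasing report
#'
#' For every band with nonzero amplitude, reports the information-spectrum
#' component at twice the band frequency, the frequency at which it would
#' be observed when the accuracy timecourse is sampled at
#' `sample_rate_hz`, and whether it is aliased. The boundary
#' `Fs = 4 * Omega` passes (the doubled frequency then sits exactly at
#' Nyquist and is still resolved).
#'
#' @param model an [evoked_spectrum_model()].
#' @param sample_rate_hz sampling rate of the accuracy timecourse in Hz.
#' @return an `alias_report`: data frame with columns `band_hz`,
#'   `info_freq_hz` (= 2 band), `sample_rate_hz`, `nyquist_hz`,
#'   `observed_freq_hz`, `is_aliased`.
#' @export
check_sampling <- function(model, sample_rate_hz) {
  stopifnot(inherits(model, "evoked_spectrum_model"))
  if (sample_rate_hz <= 0) stop("sample rate must be positive")
  nz <- apply(model$amplitudes, 1, function(a) any(a > 0))
  bands <- model$freqs_hz[nz]
  info <- 2 * bands
  obs <- alias_frequency(info, sample_rate_hz)
  rep <- data.frame(
    band_hz = bands,
    info_freq_hz = info,
    sample_rate_hz = sample_rate_hz,
    nyquist_hz = sample_rate_hz / 2,
    observed_freq_hz = obs,
    is_aliased = abs(obs - info) > 1e-9
  )
  class(rep) <- c("alias_report", "data.frame")
  rep
}

#' @export
print.alias_report <- function(x, ...) {
  cat("<alias_report>\n")
  print.data.frame(x, row.names = FALSE)
  n_bad <- sum(x$is_aliased)
  if (n_bad > 0)
    cat(sprintf("WARNING: %d band(s) produce representational aliasing; sample at >= %g Hz\n",
                n_bad, 2 * max(x$info_freq_hz)))
  else cat("no representational aliasing at this sampling rate\n")
  invisible(x)
}

#' Dominant nonzero frequency of a sampled timecourse
#'
#' FFT-based peak estimate used throughout the package to read off the
#' frequency of information timecourses: removes the mean, takes the
#' periodogram over the full (ideally integer-cycle) window, and returns
#' the non-DC frequency bin with maximum power.
#'
#' @param values sampled timecourse.
#' @param sample_rate_hz its sampling rate in Hz.
#' @return dominant frequency in Hz.
#' @export
dominant_frequency <- function(values, sample_rate_hz) {
  n <- length(values)
  if (n < 4) stop("timecourse too short for a frequency estimate")
  sp <- spectrum_table(values, sample_rate_hz)
  sp <- sp[sp$freq_hz > 0, ]
  sp$freq_hz[which.max(sp$power)]
}

#' One-sided periodogram of a timecourse
#'
#' Mean-removed FFT power on frequencies `0, df, ..., Fs/2` with
#' `df = Fs / n`.
#'
#' @inheritParams dominant_frequency
#' @return data frame with columns `freq_hz` and `power`.
#' @export
spectrum_table <- function(values, sample_rate_hz) {
  n <- length(values)
  v <- values - mean(values)
  X <- stats::fft(v)
  k <- 0:(n %/% 2)
  data.frame(freq_hz = k * sample_rate_hz / n,
             power = Mod(X[k + 1])^2 / n)
}

#' Upper edge of a spectrum's support
#'
#' Highest frequency whose power exceeds `threshold` times the peak power
#' (DC excluded), the convention used for reading information-bandwidth
#' edges off simulated spectra.
#'
#' @param spec data frame from [spectrum_table()] (or any with `freq_hz`,
#'   `power`).
#' @param threshold relative power threshold (default 0.01).
#' @return frequency in Hz.
#' @export
spectrum_support_edge <- function(spec, threshold = 0.01) {
  s <- spec[spec$freq_hz > 0, ]
  peak <- max(s$power)
  max(s$freq_hz[s$power >= threshold * peak])
}
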