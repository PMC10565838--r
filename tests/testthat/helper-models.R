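# Shared fixture builders; everything generated in code, seeded per use.

# random SPD matrix with unit-scale eigenvalues
rand_spd <- function(p) {
  M <- matrix(stats::rnorm(p * p), p)
  crossprod(M) / p + diag(p) * 0.5
}

# random multi-band model; moderate SNR so MI stays well inside (0, 1)
rand_model <- function(seed, n_channels = 3, n_bands = 2, fs = 200,
                       epoch_s = 0.5, max_freq = 20, amp_range = c(0.1, 0.8)) {
  set.seed(seed)
  freqs <- sort(sample(2:max_freq, n_bands))
  evoked_spectrum_model(
    n_channels = n_channels, sample_rate_hz = fs, epoch_length_s = epoch_s,
    freqs_hz = freqs,
    amplitudes = matrix(stats::runif(n_bands * n_channels, amp_range[1],
                                     amp_range[2]), n_bands, n_channels),
    phases = matrix(stats::runif(n_bands * n_channels, 0, 2 * pi),
                    n_bands, n_channels),
    noise_cov = replicate(n_bands, rand_spd(n_channels), simplify = FALSE))
}

# direct (brute-force) squared Mahalanobis separation oracles
direct_band_separation <- function(model, band, t) {
  b <- which(abs(model$freqs_hz - band) < 1e-9)
  S <- solve(model$noise_cov[[b]])
  sapply(t, function(tt) {
    d <- 2 * model$amplitudes[b, ] *
      cos(2 * pi * band * tt + model$phases[b, ])
    drop(t(d) %*% S %*% d)
  })
}

direct_broadband_separation <- function(model, t) {
  S <- solve(Reduce(`+`, model$noise_cov))
  sapply(t, function(tt) {
    d <- rep(0, model$n_channels)
    for (b in seq_along(model$freqs_hz))
      d <- d + 2 * model$amplitudes[b, ] *
        cos(2 * pi * model$freqs_hz[b] * tt + model$phases[b, ])
    drop(t(d) %*% S %*% d)
  })
}

# null (exchangeable-conditions) model
null_model <- function(n_channels = 2, fs = 100, epoch_s = 0.5) {
  evoked_spectrum_model(n_channels, fs, epoch_s, freqs_hz = 10,
                        amplitudes = 0, noise_cov = diag(n_channels))
}
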