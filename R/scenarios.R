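#' Canonical two-channel single-oscillation model ("example 1")
#'
#' Two channels; condition 1 evokes a phase-locked 10 Hz oscillation on
#' both channels, condition 2 is a null condition with no evoked response.
#' In the signed-label parameterisation this is amplitude `amplitude` with
#' a baseline equal to the condition-mean average, so the class-mean
#' difference is `2 * amplitude * cos(2 pi f t)` per channel. Band noise is
#' isotropic with standard deviation `noise_sd`.
#'
#' @param amplitude evoked half-difference amplitude per channel (default 1).
#' @param noise_sd band noise standard deviation (default 1).
#' @param freq_hz oscillation frequency (default 10).
#' @param sample_rate_hz sampling rate (default 100, MEG-like after
#'   downsampling).
#' @param epoch_length_s epoch length (default 0.5 s).
#' @param n_channels number of channels (default 2).
#' @return an [evoked_spectrum_model()].
#' @export
model_example1 <- function(amplitude = 1, noise_sd = 1, freq_hz = 10,
                           sample_rate_hz = 100, epoch_length_s = 0.5,
                           n_channels = 2) {
  n_time <- round(epoch_length_s * sample_rate_hz)
  t <- (seq_len(n_time) - 1) / sample_rate_hz
  baseline <- matrix(rep(amplitude * cos(2 * pi * freq_hz * t),
                         each = n_channels), n_channels, n_time)
  evoked_spectrum_model(
    n_channels = n_channels, sample_rate_hz = sample_rate_hz,
    epoch_length_s = epoch_length_s, freqs_hz = freq_hz,
    amplitudes = matrix(amplitude, 1, n_channels),
    phases = matrix(0, 1, n_channels),
    noise_cov = diag(noise_sd^2, n_channels),
    baseline_mean = baseline)
}

#' Canonical two-component model ("example 2")
#'
#' Both conditions evoke components at 10 and 15 Hz with a 20% relative
#' amplitude difference between conditions (condition means 1.1/0.9 times
#' the base amplitudes), so the class half-difference amplitudes are 10% of
#' the base. The 15 Hz component is weaker than the 10 Hz one
#' (`ratio_15` of its amplitude), which gives the characteristic
#' three-distinct-peaks information timecourse per 0.2 s fundamental
#' period; its spectrum is supported on the pairwise harmonics
#' {5, 20, 25, 30} Hz with maximum 30 Hz = 2 Omega.
#'
#' @param base_amplitude 10 Hz condition-mean base amplitude (default 1).
#' @param contrast relative condition difference (default 0.2, i.e. means
#'   at 1.1 and 0.9 times base).
#' @param ratio_15 15 Hz amplitude relative to 10 Hz (default 0.65).
#' @inheritParams model_example1
#' @return an [evoked_spectrum_model()].
#' @export
model_example2 <- function(base_amplitude = 1, contrast = 0.2,
                           ratio_15 = 0.65, noise_sd = 1,
                           sample_rate_hz = 100, epoch_length_s = 0.5,
                           n_channels = 2) {
  freqs <- c(10, 15)
  base <- base_amplitude * c(1, ratio_15)
  half_diff <- base * contrast / 2
  n_time <- round(epoch_length_s * sample_rate_hz)
  t <- (seq_len(n_time) - 1) / sample_rate_hz
  base_wave <- base[1] * cos(2 * pi * 10 * t) + base[2] * cos(2 * pi * 15 * t)
  evoked_spectrum_model(
    n_channels = n_channels, sample_rate_hz = sample_rate_hz,
    epoch_length_s = epoch_length_s, freqs_hz = freqs,
    amplitudes = matrix(half_diff, 2, n_channels),
    phases = matrix(0, 2, n_channels),
    noise_cov = rep(list(diag(noise_sd^2, n_channels)), 2),
    baseline_mean = matrix(rep(base_wave, each = n_channels),
                           n_channels, n_time))
}

#' Local maxima with a topographic prominence threshold
#'
#' Finds local maxima of a (optionally periodic) sampled curve whose
#' topographic prominence is at least `prominence_frac` times the global
#' maximum — the convention used for counting "distinct peaks" in the
#' scenario outputs.
#'
#' @param values sampled curve.
#' @param prominence_frac prominence threshold relative to the global
#'   maximum (default 0.1).
#' @param periodic treat the curve as one period of a periodic signal
#'   (default FALSE).
#' @return integer indices of the prominent peaks.
#' @export
find_peaks <- function(values, prominence_frac = 0.1, periodic = FALSE) {
  v <- as.numeric(values)
  n <- length(v)
  if (periodic) {
    gl <- v[c(n, 1:(n - 1))]; gr <- v[c(2:n, 1)]
  } else {
    gl <- c(-Inf, v[-n]); gr <- c(v[-1], -Inf)
  }
  pk <- which(v > gl & v >= gr)
  gmax <- max(v)
  keep <- vapply(pk, function(i) {
    if (v[i] == gmax) return(TRUE)
    mins <- c(-Inf, -Inf)
    for (d in 1:2) {
      j <- i; m <- v[i]
      for (s in seq_len(n - 1)) {
        j2 <- j + c(-1, 1)[d]
        if (periodic) j2 <- ((j2 - 1) %% n) + 1
        else if (j2 < 1 || j2 > n) break
        j <- j2
        m <- min(m, v[j])
        if (v[j] > v[i]) { mins[d] <- m; break }
        mins[d] <- m
      }
    }
    (v[i] - max(mins[is.finite(mins)], -Inf)) >= prominence_frac * gmax
  }, logical(1))
  pk[keep]
}

.scenario_result <- function(name, model, info_timecourses, spectra,
                             decoding = NULL, provenance = list()) {
  structure(list(name = name, model = model,
                 info_timecourses = info_timecourses, spectra = spectra,
                 decoding = decoding,
                 provenance = c(provenance,
                                list(package_version = as.character(utils::packageVersion("repdyn"))))),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s'\n", x$name))
  cat("  timecourses:", paste(names(x$info_timecourses), collapse = ", "), "\n")
  cat("  spectra:", paste(names(x$spectra), collapse = ", "), "\n")
  if (!is.null(x$provenance$summary)) cat(" ", x$provenance$summary, "\n")
  invisible(x)
}

#' Frequency-doubling scenario (single 10 Hz component)
#'
#' Builds the example-1 model, computes the evoked waveforms, the analytic
#' broadband mutual-information timecourse on a fine integer-cycle grid,
#' and its spectrum. The only evoked oscillation is at 10 Hz, but the
#' information timecourse oscillates at 20 Hz, peaking at every peak and
#' trough of the evoked response. Optionally decodes simulated trials to
#' compare empirical accuracy peaks against the analytic MI peaks.
#'
#' @param amplitude,noise_sd model parameters (see [model_example1()]).
#' @param decode also simulate `n_trials` trials and run
#'   [decode_instantaneous()] (default FALSE).
#' @param n_trials,seed simulation size and seed when `decode = TRUE`.
#' @return a `scenario_result` with `info_timecourses$broadband_mi`,
#'   `spectra$mi` and `provenance$dominant_freq_hz` (= 20).
#' @export
scenario_example1 <- function(amplitude = 1, noise_sd = 1, decode = FALSE,
                              n_trials = 200, seed = 1) {
  model <- model_example1(amplitude, noise_sd)
  grid_fs <- 400
  tg <- seq(0, 1 - 1 / grid_fs, by = 1 / grid_fs)  # integer number of 20 Hz cycles
  mi <- broadband_info_timecourse(model, time_s = tg)
  spec <- spectrum_table(mi$value, grid_fs)
  dom <- dominant_frequency(mi$value, grid_fs)
  decoding <- NULL
  if (decode) {
    ds <- simulate_trials(model, n_trials, seed)
    decoding <- list(instantaneous = decode_instantaneous(ds, seed = seed))
  }
  .scenario_result(
    "example1", model,
    list(broadband_mi = mi,
         evoked_pos = evoked_waveform(model, 1),
         evoked_neg = evoked_waveform(model, -1)),
    list(mi = spec),
    decoding,
    list(seed = seed, grid_fs = grid_fs, dominant_freq_hz = dom,
         summary = sprintf("10 Hz evoked component -> dominant information frequency %g Hz", dom)))
}

#' Broadband harmonic scenario (10 + 15 Hz components)
#'
#' Builds the example-2 model and computes the analytic broadband MI
#' timecourse over integer fundamental periods. Its spectrum is supported
#' on the pairwise sum/difference harmonics {5, 20, 25, 30} Hz (plus DC),
#' and the timecourse shows three distinct peaks per 0.2 s fundamental
#' period.
#'
#' @param ... passed to [model_example2()].
#' @return a `scenario_result`; `provenance$support_hz` lists the nonzero
#'   supported frequencies, `provenance$n_peaks_per_period` the prominent
#'   peak count in one fundamental period.
#' @export
scenario_example2 <- function(...) {
  model <- model_example2(...)
  grid_fs <- 400
  tg <- seq(0, 1 - 1 / grid_fs, by = 1 / grid_fs)  # 5 fundamental periods
  mi <- broadband_info_timecourse(model, time_s = tg)
  spec <- spectrum_table(mi$value, grid_fs)
  nz <- spec[spec$freq_hz > 0 & spec$power >= 0.01 * max(spec$power[spec$freq_hz > 0]), ]
  one_period <- mi$value[tg < 0.2]
  peaks <- find_peaks(one_period, periodic = TRUE)
  .scenario_result(
    "example2", model,
    list(broadband_mi = mi),
    list(mi = spec),
    NULL,
    list(grid_fs = grid_fs, support_hz = nz$freq_hz,
         max_freq_hz = max(nz$freq_hz),
         n_peaks_per_period = length(peaks),
         summary = sprintf("harmonics at %s Hz; %d peaks per fundamental period",
                           paste(nz$freq_hz, collapse = ", "), length(peaks))))
}

#' Representational-aliasing scenario
#'
#' Samples the example-1 analytic MI timecourse (a 20 Hz information
#' signal) at each requested rate over an integer number of information
#' cycles and estimates the dominant recovered frequency by FFT peak. Rates
#' of at least 4 Omega (40 Hz here) recover the true 20 Hz; lower rates
#' fold it — at 30 Hz it appears at 10 Hz.
#'
#' @param sample_rates sampling rates of the accuracy/information
#'   timecourse in Hz (default `c(160, 30)` as in the faithful/aliased
#'   comparison).
#' @param duration_s sampling window (default 1 s: integer cycles at the
#'   default rates).
#' @return a `scenario_result`; `provenance$recovered` is a data frame
#'   with `sample_rate_hz`, `recovered_freq_hz`, `predicted_freq_hz`
#'   (= `alias_frequency(20, Fs)`).
#' @export
scenario_aliasing <- function(sample_rates = c(160, 30), duration_s = 1) {
  model <- model_example1()
  info_f <- info_bandwidth(model)  # 20 Hz
  out <- lapply(sample_rates, function(fs) {
    tg <- seq(0, duration_s - 1 / fs, by = 1 / fs)
    mi <- broadband_info_timecourse(model, time_s = tg)
    list(fs = fs, mi = mi,
         recovered = dominant_frequency(mi$value, fs),
         predicted = alias_frequency(info_f, fs))
  })
  rec <- data.frame(
    sample_rate_hz = sample_rates,
    recovered_freq_hz = vapply(out, `[[`, numeric(1), "recovered"),
    predicted_freq_hz = vapply(out, `[[`, numeric(1), "predicted"))
  tcs <- stats::setNames(lapply(out, `[[`, "mi"),
                         sprintf("mi_fs%g", sample_rates))
  .scenario_result(
    "aliasing", model, tcs,
    list(),
    NULL,
    list(recovered = rec,
         summary = paste(sprintf("Fs=%g -> %g Hz", rec$sample_rate_hz,
                                 rec$recovered_freq_hz), collapse = "; ")))
}

# smooth 0->1 raised-cosine ramp starting at t0, width w
.cos_ramp <- function(t, t0, w) {
  ifelse(t < t0, 0, ifelse(t > t0 + w, 1, 0.5 - 0.5 * cos(pi * (t - t0) / w)))
}

# class-mean-difference waveforms (channels x time) for the nonstationary
# scenarios, on a fine grid
.chirp_waveform <- function(t, amplitude, f0, f1, epoch_s, step_t, step_w,
                            edge_w) {
  k <- (f1 - f0) / epoch_s
  ph <- 2 * pi * (f0 * t + k / 2 * t^2)
  env <- .cos_ramp(t, 0, edge_w) * (1 - .cos_ramp(t, epoch_s - edge_w, edge_w))
  ch1 <- amplitude * env * sin(ph)
  ch2 <- amplitude * env * .cos_ramp(t, step_t, step_w) * sin(ph)
  rbind(ch1, ch2)
}

# broadband MI timecourse for an arbitrary mean-difference waveform with
# isotropic broadband noise
.waveform_mi <- function(diff_wave, noise_sd) {
  link_mi(colSums((diff_wave / noise_sd)^2))
}

# complex-spectrum MI map of an arbitrary mean-difference waveform:
# STFT of the difference per channel; per-band circular noise variances
# derived from the window taper; MI per band and timepoint.
.waveform_complex_map <- function(diff_wave, fs, noise_sd, window_ms) {
  P <- nrow(diff_wave)
  arr <- array(0, dim = c(1, P, ncol(diff_wave)))
  arr[1, , ] <- diff_wave
  ds <- trial_dataset(arr, labels = 1L, sample_rate_hz = fs)
  sf <- stft_epochs(ds, window_ms = window_ms)
  L <- round(window_ms / 1000 * fs)
  win <- .stft_window("hamming", L)
  n_idx <- 0:(L - 1); c0 <- L %/% 2
  nb <- length(sf$band_hz)
  d2 <- matrix(0, nb, dim(sf$coeffs)[4])
  for (b in seq_len(nb)) {
    k <- b - 1
    scale <- if (sf$band_hz[b] == 0 || (L %% 2 == 0 && b == nb)) 1 / sum(win)
             else 2 / sum(win)
    th <- 2 * pi * k * (n_idx - c0) / L
    var_re <- scale^2 * noise_sd^2 * sum((win * cos(th))^2)
    var_im <- scale^2 * noise_sd^2 * sum((win * sin(th))^2)
    for (p in seq_len(P)) {
      cf <- sf$coeffs[1, p, b, ]
      d2[b, ] <- d2[b, ] + Re(cf)^2 / var_re +
        if (var_im > 1e-30) Im(cf)^2 / var_im else 0
    }
  }
  list(band_hz = sf$band_hz, time_s = sf$time_s,
       mi = matrix(link_mi(as.numeric(d2)), nb, ncol(d2)), d2 = d2)
}

#' Non-stationary chirp scenario
#'
#' Condition 1 evokes a linear frequency chirp (default 5 to 50 Hz over
#' the 0.5 s epoch) on channel 1, and the same chirp gated by a smoothed
#' unit step at 0.2 s on channel 2; condition 2 is null. Signal content is
#' confined below 50 Hz, yet the broadband information timecourse — the
#' squared separation passed through the information link — has spectral
#' support extending to about 100 Hz, double the signal's maximum
#' instantaneous frequency. The complex-spectrum information map (50 ms
#' sliding Hamming window) instead peaks along the chirp's true
#' time-frequency ridge.
#'
#' @param amplitude chirp half-difference amplitude (default 0.5; keeps the
#'   information link in its near-linear range so the spectrum reflects the
#'   separation structure rather than saturation).
#' @param noise_sd broadband noise standard deviation (default 1).
#' @param f0,f1 chirp start/end instantaneous frequency in Hz.
#' @param window_ms complex-map STFT window (default 50).
#' @param grid_fs analysis grid rate in Hz (default 400).
#' @return a `scenario_result`; `provenance$support_edge_hz` gives the
#'   upper 1%-power edge of the broadband MI spectrum, `spectra$mi_map`
#'   the complex-spectrum information map.
#' @export
scenario_chirp <- function(amplitude = 0.5, noise_sd = 1, f0 = 5, f1 = 50,
                           window_ms = 50, grid_fs = 400) {
  epoch_s <- 0.5
  t <- seq(0, epoch_s - 1 / grid_fs, by = 1 / grid_fs)
  s <- .chirp_waveform(t, 2 * amplitude, f0, f1, epoch_s,
                       step_t = 0.2, step_w = 0.03, edge_w = 0.05)
  mi <- .info_timecourse(t, .waveform_mi(s, noise_sd),
                         "mutual_information_bits", "broadband")
  spec <- spectrum_table(mi$value, grid_fs)
  edge <- spectrum_support_edge(spec)
  map <- .waveform_complex_map(s, grid_fs, noise_sd, window_ms)
  ridge <- map$band_hz[apply(map$mi, 2, which.max)]
  .scenario_result(
    "chirp", list(diff_waveform = s, time_s = t, noise_sd = noise_sd),
    list(broadband_mi = mi),
    list(mi = spec, mi_map = map),
    NULL,
    list(grid_fs = grid_fs, support_edge_hz = edge, ridge_hz = ridge,
         f_instantaneous = f0 + (f1 - f0) * t / epoch_s,
         summary = sprintf("signal content < %g Hz; information support edge %g Hz",
                           f1, edge)))
}

#' Non-oscillatory two-activation scenario
#'
#' Condition 1 evokes two spatially and temporally distinct transient
#' activations — Gaussian kernels (default sd 30 ms) centred at 0.15 s on
#' channel 1 and 0.35 s on channel 2; condition 2 is null. The broadband
#' information timecourse shows two distinct peaks, one per activation. The
#' complex-spectrum information (summed over bands) reproduces both peaks
#' when the sliding window is shorter than the activation spacing; wider
#' windows progressively merge them (reduced peak separation/prominence).
#'
#' @param window_ms_list STFT window lengths to compare (default
#'   `c(50, 200)`).
#' @param amplitude activation half-difference amplitude (default 1).
#' @param noise_sd broadband noise sd (default 1).
#' @param centers_s activation centres in seconds (default `c(0.15, 0.35)`).
#' @param sd_ms Gaussian kernel standard deviation (default 30 ms).
#' @param grid_fs analysis grid rate (default 200 Hz).
#' @return a `scenario_result`; `provenance$peaks` records the prominent
#'   broadband peaks, `spectra$complex_mi` the per-window complex
#'   timecourses with their peak structure.
#' @export
scenario_activations <- function(window_ms_list = c(50, 200), amplitude = 1,
                                 noise_sd = 1, centers_s = c(0.15, 0.35),
                                 sd_ms = 30, grid_fs = 200) {
  epoch_s <- 0.5
  t <- seq(0, epoch_s - 1 / grid_fs, by = 1 / grid_fs)
  P <- length(centers_s)
  s <- do.call(rbind, lapply(centers_s, function(c0)
    2 * amplitude * exp(-0.5 * ((t - c0) / (sd_ms / 1000))^2)))
  mi <- .info_timecourse(t, .waveform_mi(s, noise_sd),
                         "mutual_information_bits", "broadband")
  bb_peaks <- find_peaks(mi$value)
  complex_mi <- lapply(window_ms_list, function(wm) {
    map <- .waveform_complex_map(s, grid_fs, noise_sd, wm)
    tot <- link_mi(colSums(map$d2))
    pk <- find_peaks(tot)
    # peak pronouncedness: depth of the valley between the outermost peaks
    # relative to the weaker peak; 0 when the peaks have merged
    pron <- if (length(pk) >= 2) {
      valley <- min(tot[min(pk):max(pk)])
      (min(tot[pk]) - valley) / min(tot[pk])
    } else 0
    list(window_ms = wm, time_s = map$time_s, value = tot, peaks = pk,
         peak_times = map$time_s[pk], pronouncedness = pron)
  })
  names(complex_mi) <- sprintf("window_%gms", window_ms_list)
  .scenario_result(
    "activations", list(diff_waveform = s, time_s = t, noise_sd = noise_sd),
    list(broadband_mi = mi),
    list(complex_mi = complex_mi),
    NULL,
    list(grid_fs = grid_fs, broadband_peak_times = t[bb_peaks],
         summary = sprintf("broadband peaks at %s s",
                           paste(round(t[bb_peaks], 3), collapse = ", "))))
}
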