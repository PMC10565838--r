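#' Two-condition generative model of evoked responses
#'
#' Constructs the parameterisation of a two-condition generative model for
#' epoched multichannel data. Each trial is a condition-independent baseline
#' plus a condition-signed sum of phase-locked sinusoidal components
#' ("evoked" terms) and stationary narrowband Gaussian residuals. Writing
#' the per-band complex coefficient of trial n as
#' \deqn{w_{n,t,\omega} = y_n A_\omega e^{i(\omega t + \phi_\omega)} +
#'       \epsilon_{n,\omega} e^{i\omega t},}
#' with \eqn{\epsilon_{n,\omega}} having independent Gaussian real and
#' imaginary parts of covariance \eqn{\Sigma_\omega}, the observed signal is
#' the baseline plus the sum over bands of \eqn{Re(w_{n,t,\omega})}. Labels
#' are \eqn{y_n \in \{+1, -1\}} with equal priors, so the class-conditional
#' distribution of the broadband signal at time t is Gaussian with mean
#' \eqn{\mu_t + y \sum_\omega A_\omega \cos(\omega t + \phi_\omega)} and
#' covariance \eqn{\sum_\omega \Sigma_\omega}.
#'
#' @param n_channels number of channels (P).
#' @param sample_rate_hz sampling rate in Hz.
#' @param epoch_length_s epoch duration in seconds; the time grid is
#'   `(0:(T-1))/sample_rate_hz` with `T = round(epoch_length_s * sample_rate_hz)`
#'   and t = 0 at stimulus onset.
#' @param freqs_hz vector of component frequencies in Hz (must not exceed
#'   the Nyquist frequency).
#' @param amplitudes per-band amplitudes: a matrix with one row per
#'   frequency and one column per channel (a scalar or length-P vector per
#'   band is recycled). Entries are the half-difference of the two
#'   condition means, so the class-mean difference in band omega is
#'   `2 * amplitudes * cos(...)`. All entries must be non-negative.
#' @param phases per-band, per-channel phase offsets in radians; wrapped
#'   into `[0, 2*pi)`. Recycled like `amplitudes`.
#' @param noise_cov a single P x P symmetric positive-definite matrix used
#'   for every band, or a list with one such matrix per band.
#' @param baseline_mean optional condition-independent mean, a P x T matrix
#'   (default all zeros; it cancels from every information quantity).
#' @param induced optional per-band, per-condition scaling of the residual
#'   amplitude: a matrix with one row per band and two columns (scaling for
#'   condition +1 and condition -1). Models condition-dependent bandlimited
#'   power with random phase ("induced" effects). Default: no scaling.
#'
#' @return an object of class `evoked_spectrum_model`.
#' @seealso [build_model()] for construction from a config list or file,
#'   [evoked_waveform()], [simulate_trials()].
#' @export
evoked_spectrum_model <- function(n_channels, sample_rate_hz, epoch_length_s,
                                  freqs_hz = numeric(0),
                                  amplitudes = NULL, phases = NULL,
                                  noise_cov = NULL, baseline_mean = NULL,
                                  induced = NULL) {
  stopifnot(length(n_channels) == 1, n_channels >= 1,
            length(sample_rate_hz) == 1, sample_rate_hz > 0,
            length(epoch_length_s) == 1, epoch_length_s > 0)
  P <- as.integer(n_channels)
  n_bands <- length(freqs_hz)
  n_time <- as.integer(round(epoch_length_s * sample_rate_hz))
  if (n_time < 1) stop("epoch shorter than one sample")
  if (any(freqs_hz < 0)) stop("negative frequency not allowed")
  if (any(freqs_hz > sample_rate_hz / 2)) {
    bad <- freqs_hz[freqs_hz > sample_rate_hz / 2][1]
    stop(sprintf("frequency %g Hz exceeds the Nyquist frequency %g Hz",
                 bad, sample_rate_hz / 2))
  }

  amplitudes <- .band_channel_matrix(amplitudes, n_bands, P, default = 0,
                                     what = "amplitudes")
  phases <- .band_channel_matrix(phases, n_bands, P, default = 0,
                                 what = "phases")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  phases <- phases %% (2 * pi)

  if (is.null(noise_cov)) noise_cov <- diag(P)
  if (is.matrix(noise_cov)) noise_cov <- rep(list(noise_cov), max(n_bands, 1))
  if (n_bands > 0 && length(noise_cov) != n_bands)
    stop("need one noise covariance per frequency band")
  noise_cov <- lapply(noise_cov, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (b in seq_along(noise_cov)) {
    m <- noise_cov[[b]]
    if (!all(dim(m) == c(P, P)))
      stop(sprintf("noise covariance for band %g Hz is not %d x %d",
                   freqs_hz[b], P, P))
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      stop(sprintf("noise covariance for band %g Hz is not symmetric",
                   freqs_hz[b]))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf(
        "noise covariance for band %g Hz is not positive definite (min eigenvalue %g)",
        freqs_hz[b], min(ev)))
  }

  if (is.null(baseline_mean)) baseline_mean <- matrix(0, P, n_time)
  baseline_mean <- as.matrix(baseline_mean)
  if (!all(dim(baseline_mean) == c(P, n_time)))
    stop(sprintf("baseline_mean must be %d x %d (channels x timepoints)",
                 P, n_time))

  if (!is.null(induced)) {
    induced <- matrix(as.numeric(induced), nrow = n_bands, ncol = 2)
    if (any(induced <= 0)) stop("induced scalings must be positive")
  }

  structure(list(
    n_channels = P,
    sample_rate_hz = sample_rate_hz,
    epoch_length_s = epoch_length_s,
    n_time = n_time,
    time_s = (seq_len(n_time) - 1) / sample_rate_hz,
    freqs_hz = as.numeric(freqs_hz),
    amplitudes = amplitudes,
    phases = phases,
    noise_cov = noise_cov,
    baseline_mean = baseline_mean,
    induced = induced
  ), class = "evoked_spectrum_model")
}

.band_channel_matrix <- function(x, n_bands, P, default, what) {
  if (n_bands == 0) return(matrix(numeric(0), 0, P))
  if (is.null(x)) x <- default
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(v) rep_len(v, P)))
  if (!is.matrix(x)) {
    if (length(x) == 1) x <- matrix(x, n_bands, P)
    else if (length(x) == n_bands) x <- matrix(x, n_bands, P)
    else if (length(x) == P) x <- matrix(x, n_bands, P, byrow = TRUE)
    else stop(sprintf("cannot interpret %s of length %d", what, length(x)))
  }
  if (!all(dim(x) == c(n_bands, P)))
    stop(sprintf("%s must be a %d x %d (band x channel) matrix",
                 what, n_bands, P))
  storage.mode(x) <- "double"
  x
}

#' @export
print.evoked_spectrum_model <- function(x, ...) {
  cat(sprintf("<evoked_spectrum_model> %d channel(s), %g Hz, %.3g s epoch (%d samples)\n",
              x$n_channels, x$sample_rate_hz, x$epoch_length_s, x$n_time))
  if (length(x$freqs_hz)) {
    cat(sprintf("  bands (Hz): %s\n", paste(x$freqs_hz, collapse = ", ")))
    cat(sprintf("  max |amplitude|: %g\n", max(x$amplitudes)))
  } else cat("  no evoked components\n")
  if (!is.null(x$induced)) cat("  induced (condition-dependent power) scaling present\n")
  invisible(x)
}

#' Build a model from a configuration mapping or file
#'
#' Accepts either a named list or the path of a JSON/YAML file with fields
#' `n_channels`, `sample_rate_hz`, `epoch_length_s`, an optional global
#' `noise_var` (identity covariance scaling used where a component omits its
#' own covariance; default 1), and a `components` list whose entries each
#' supply `freq_hz` plus optional `amplitude`, `phase`, `noise_cov` (P x P,
#' row-major nested list in files), and `induced_scale` (length 2).
#'
#' @param config named list or path to a `.json`/`.yaml`/`.yml` file.
#' @return a validated [evoked_spectrum_model()].
#' @export
build_model <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_model_config(config)
  }
  stopifnot(is.list(config))
  need <- c("n_channels", "sample_rate_hz", "epoch_length_s")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  P <- as.integer(config$n_channels)
  noise_var <- if (is.null(config$noise_var)) 1 else config$noise_var
  comps <- config$components
  if (is.null(comps)) comps <- list()
  freqs <- vapply(comps, function(cc) as.numeric(cc$freq_hz), numeric(1))
  amps <- lapply(comps, function(cc) {
    if (is.null(cc$amplitude)) rep(0, P) else rep_len(as.numeric(cc$amplitude), P)
  })
  phs <- lapply(comps, function(cc) {
    if (is.null(cc$phase)) rep(0, P) else rep_len(as.numeric(cc$phase), P)
  })
  covs <- lapply(comps, function(cc) {
    if (is.null(cc$noise_cov)) diag(noise_var, P)
    else {
      m <- cc$noise_cov
      if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
      as.matrix(m)
    }
  })
  induced <- NULL
  if (any(vapply(comps, function(cc) !is.null(cc$induced_scale), logical(1)))) {
    induced <- do.call(rbind, lapply(comps, function(cc) {
      if (is.null(cc$induced_scale)) c(1, 1) else rep_len(as.numeric(cc$induced_scale), 2)
    }))
  }
  baseline <- config$baseline_mean
  if (!is.null(baseline) && is.list(baseline))
    baseline <- do.call(rbind, lapply(baseline, as.numeric))
  evoked_spectrum_model(
    n_channels = P,
    sample_rate_hz = config$sample_rate_hz,
    epoch_length_s = config$epoch_length_s,
    freqs_hz = freqs,
    amplitudes = if (length(amps)) do.call(rbind, amps) else NULL,
    phases = if (length(phs)) do.call(rbind, phs) else NULL,
    noise_cov = if (length(covs)) covs else diag(noise_var, P),
    baseline_mean = baseline,
    induced = induced
  )
}

#' Read a model configuration file (JSON or YAML)
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return the configuration as a named list (see [build_model()]).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext)
  }
}

#' Noise-free class-conditional mean waveform
#'
#' Evaluates the evoked (phase-locked) part of the model for one condition:
#' baseline plus `label` times the sum over bands of
#' `amplitude * cos(2*pi*f*t + phase)`. Deterministic; the class-mean
#' difference is twice the evoked sum.
#'
#' @param model an [evoked_spectrum_model()].
#' @param label condition label, `+1` or `-1`.
#' @return a channels x time matrix on the model's time grid.
#' @export
evoked_waveform <- function(model, label) {
  stopifnot(inherits(model, "evoked_spectrum_model"))
  if (!label %in% c(-1, 1)) stop("label must be +1 or -1")
  out <- model$baseline_mean
  t <- model$time_s
  for (b in seq_along(model$freqs_hz)) {
    w <- 2 * pi * model$freqs_hz[b]
    # channels x time: a_i cos(w t + phi_i)
    out <- out + label * (model$amplitudes[b, ] *
      cos(outer(model$phases[b, ], w * t, "+")))
  }
  out
}

#' Simulate a balanced set of epoched trials
#'
#' Labels alternate `+1, -1, ...` (exactly balanced design, equal class
#' priors). Each trial adds, per band, the real part of a stationary
#' narrowband residual: a complex Gaussian coefficient
#' `eps = N(0, Sigma) + i N(0, Sigma)` drawn once per trial per band and
#' rotated around the epoch as `eps * exp(i*w*t)` — so residual amplitude is
#' fixed within a trial and residual phase is uniform over trials. If the
#' model carries `induced` scalings, the residual of a trial in condition y
#' is multiplied by the band's condition-y scaling, giving
#' condition-dependent bandlimited power with stimulus-random phase.
#'
#' @param model an [evoked_spectrum_model()].
#' @param n_trials even, positive number of trials.
#' @param seed integer seed; the simulation is bit-reproducible given
#'   (model, n_trials, seed).
#' @return a `trial_dataset`: list with `data` (trials x channels x time
#'   array), `labels` (+1/-1), `sample_rate_hz`, `time_s`, and `meta`
#'   (provenance: seed, trial count, model summary).
#' @export
simulate_trials <- function(model, n_trials, seed) {
  stopifnot(inherits(model, "evoked_spectrum_model"))
  if (n_trials <= 0) stop("n_trials must be positive")
  if (n_trials %% 2 != 0) stop("n_trials must be even (balanced design)")
  set.seed(seed)
  N <- as.integer(n_trials)
  P <- model$n_channels
  Tn <- model$n_time
  labels <- rep(c(1L, -1L), N / 2)

  data <- array(0, dim = c(N, P, Tn))
  wav_pos <- evoked_waveform(model, 1L)
  wav_neg <- evoked_waveform(model, -1L)
  for (n in seq_len(N)) {
    data[n, , ] <- if (labels[n] == 1L) wav_pos else wav_neg
  }

  t <- model$time_s
  for (b in seq_along(model$freqs_hz)) {
    w <- 2 * pi * model$freqs_hz[b]
    R <- chol(model$noise_cov[[b]])
    eps_re <- matrix(stats::rnorm(N * P), N, P) %*% R
    eps_im <- matrix(stats::rnorm(N * P), N, P) %*% R
    if (!is.null(model$induced)) {
      sc <- ifelse(labels == 1L, model$induced[b, 1], model$induced[b, 2])
      eps_re <- eps_re * sc
      eps_im <- eps_im * sc
    }
    cwt <- cos(w * t)
    swt <- sin(w * t)
    # Re(eps e^{iwt}) = Re(eps) cos(wt) - Im(eps) sin(wt), per trial/channel
    for (p in seq_len(P)) {
      data[, p, ] <- data[, p, ] + outer(eps_re[, p], cwt) - outer(eps_im[, p], swt)
    }
  }

  structure(list(
    data = data,
    labels = labels,
    sample_rate_hz = model$sample_rate_hz,
    time_s = t,
    meta = list(
      seed = seed,
      n_trials = N,
      n_channels = P,
      freqs_hz = model$freqs_hz,
      epoch_length_s = model$epoch_length_s,
      generator = "repdyn::simulate_trials"
    )
  ), class = "trial_dataset")
}

#' Construct a trial dataset from components
#'
#' Low-level constructor validating the invariants of the epoched-data
#' container: array dimensions consistent with labels and time axis, and
#' labels restricted to +1/-1.
#'
#' @param data trials x channels x time numeric array.
#' @param labels vector of +1/-1 labels, one per trial.
#' @param sample_rate_hz sampling rate in Hz.
#' @param time_s optional time axis (seconds, t = 0 at onset); derived from
#'   the sampling rate when omitted.
#' @param meta free-form provenance list.
#' @return a `trial_dataset`.
#' @export
trial_dataset <- function(data, labels, sample_rate_hz, time_s = NULL,
                          meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("data must be a trials x channels x time array")
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must contain only +1 and -1")
  if (length(labels) != dim(data)[1])
    stop("labels length does not match the number of trials")
  if (is.null(time_s)) time_s <- (seq_len(dim(data)[3]) - 1) / sample_rate_hz
  if (length(time_s) != dim(data)[3])
    stop("time axis length does not match the number of timepoints")
  structure(list(data = data, labels = labels,
                 sample_rate_hz = sample_rate_hz,
                 time_s = as.numeric(time_s), meta = meta),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_dataset> %d trials x %d channels x %d timepoints @ %g Hz\n",
              d[1], d[2], d[3], x$sample_rate_hz))
  cat(sprintf("  labels: %d x +1, %d x -1\n", sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}
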