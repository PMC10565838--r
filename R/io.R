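#' Write an epoched trial dataset to disk
#'
#' Persists the dataset as an Apache Arrow IPC (Feather V2) file — a
#' standard binary columnar scientific container with exact float64
#' round-trip — together with a JSON metadata sidecar (`<path>.json`)
#' carrying the axis sizes, sampling rate and provenance. The table holds
#' one row per (trial, channel, timepoint) with columns `trial`, `channel`,
#' `time_index`, `value`, plus per-trial `label` and per-timepoint `time_s`.
#'
#' @param dataset a `trial_dataset` (see [trial_dataset()]).
#' @param path output file path (conventionally `.feather` / `.arrow`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  d <- dim(dataset$data)
  idx <- expand.grid(trial = seq_len(d[1]), channel = seq_len(d[2]),
                     time_index = seq_len(d[3]))
  tab <- data.frame(
    trial = as.integer(idx$trial),
    channel = as.integer(idx$channel),
    time_index = as.integer(idx$time_index),
    value = as.numeric(dataset$data),
    label = dataset$labels[idx$trial],
    time_s = dataset$time_s[idx$time_index]
  )
  arrow::write_feather(tab, path)
  sidecar <- list(
    format = "repdyn-trial-dataset",
    version = 1L,
    n_trials = d[1], n_channels = d[2], n_time = d[3],
    sample_rate_hz = dataset$sample_rate_hz,
    meta = dataset$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an epoched trial dataset from disk
#'
#' Inverse of [write_dataset()]; the round trip is bit-exact for the data
#' array, labels and time axis. Fails with the missing field named when the
#' container or its sidecar is malformed.
#'
#' @param path path written by [write_dataset()].
#' @return a `trial_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset container not found: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("metadata sidecar not found: ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("n_trials", "n_channels", "n_time", "sample_rate_hz"))
    if (is.null(side[[f]])) stop("sidecar missing field: ", f)
  tab <- as.data.frame(arrow::read_feather(path))
  for (f in c("trial", "channel", "time_index", "value", "label", "time_s"))
    if (is.null(tab[[f]])) stop("container missing column: ", f)
  d <- c(side$n_trials, side$n_channels, side$n_time)
  if (nrow(tab) != prod(d))
    stop(sprintf("container has %d rows, sidecar implies %d", nrow(tab), prod(d)))
  ord <- order(tab$time_index, tab$channel, tab$trial)
  tab <- tab[ord, ]
  data <- array(tab$value, dim = d)
  labels <- tab$label[match(seq_len(d[1]), tab$trial)]
  if (!all(labels %in% c(-1, 1))) stop("container column 'label' must be +1/-1")
  time_s <- tab$time_s[match(seq_len(d[3]), tab$time_index)]
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  trial_dataset(data, labels, side$sample_rate_hz, time_s, meta)
}

#' Write STFT features to disk
#'
#' Persists a `spectral_features` object in the same Arrow IPC + JSON
#' sidecar container as [write_dataset()], with the complex coefficients
#' stored as paired float64 columns (`re`, `im`).
#'
#' @param features a `spectral_features` object (see [stft_epochs()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "spectral_features"))
  d <- dim(features$coeffs)
  idx <- expand.grid(trial = seq_len(d[1]), channel = seq_len(d[2]),
                     band = seq_len(d[3]), time_index = seq_len(d[4]))
  tab <- data.frame(
    trial = as.integer(idx$trial), channel = as.integer(idx$channel),
    band = as.integer(idx$band), time_index = as.integer(idx$time_index),
    re = Re(as.vector(features$coeffs)),
    im = Im(as.vector(features$coeffs)))
  arrow::write_feather(tab, path)
  side <- list(format = "repdyn-spectral-features", version = 1L,
               dims = d, band_hz = features$band_hz,
               window_ms = features$window_ms,
               window_shape = features$window_shape,
               hop_samples = features$hop_samples,
               padding = features$padding,
               sample_rate_hz = features$sample_rate_hz,
               time_s = features$time_s, labels = features$labels)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read STFT features from disk
#'
#' Inverse of [write_features()]; bit-exact for coefficients, axes and
#' labels.
#'
#' @param path path written by [write_features()].
#' @return a `spectral_features` object.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature container not found: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("metadata sidecar not found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (f in c("dims", "band_hz", "window_ms", "sample_rate_hz", "time_s",
              "labels"))
    if (is.null(side[[f]])) stop("sidecar missing field: ", f)
  tab <- as.data.frame(arrow::read_feather(path))
  for (f in c("trial", "channel", "band", "time_index", "re", "im"))
    if (is.null(tab[[f]])) stop("container missing column: ", f)
  d <- side$dims
  if (nrow(tab) != prod(d))
    stop(sprintf("container has %d rows, sidecar implies %d",
                 nrow(tab), prod(d)))
  tab <- tab[order(tab$time_index, tab$band, tab$channel, tab$trial), ]
  structure(list(
    coeffs = array(complex(real = tab$re, imaginary = tab$im), dim = d),
    band_hz = side$band_hz, window_ms = side$window_ms,
    window_shape = side$window_shape,
    hop_samples = as.integer(side$hop_samples), padding = side$padding,
    sample_rate_hz = side$sample_rate_hz, time_s = side$time_s,
    labels = as.integer(side$labels)
  ), class = "spectral_features")
}

#' Export an information timecourse as CSV
#'
#' Writes columns `time_s`, `value`, `metric`, `scope` so published
#' timecourse figures can be regenerated outside R.
#'
#' @param tc an `info_timecourse` (see [narrowband_info_timecourse()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_info_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "info_timecourse"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.info_timecourse <- function(x, ...) {
  data.frame(time_s = x$time_s, value = x$value,
             metric = x$metric, scope = x$scope)
}
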