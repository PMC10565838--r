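#' @keywords internal
#' Stratified fold assignment shared across timepoints of one run.
.stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Cross-validated linear max-margin decoding of per-timepoint feature arrays.
# X: trials x features x time; one SVM (linear kernel, cost 1) per
# timepoint per fold, features standardized on the training fold.
.cv_decode_timecourse <- function(X, labels, n_folds, seed,
                                  return_decision = FALSE) {
  N <- dim(X)[1]
  Tn <- dim(X)[3]
  if (length(unique(labels)) < 2) stop("need both classes present")
  tab <- table(labels)
  if (min(tab) < 2 * n_folds)
    stop("need at least 2 trials per class per fold")
  fold <- .stratified_folds(labels, n_folds, seed)
  per_fold <- matrix(NA_real_, n_folds, Tn)
  decision <- if (return_decision) matrix(NA_real_, N, Tn) else NULL
  y <- factor(labels, levels = c(-1, 1))
  for (tt in seq_len(Tn)) {
    Xt <- X[, , tt, drop = FALSE]
    dim(Xt) <- dim(X)[1:2]
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      mu <- colMeans(Xt[tr, , drop = FALSE])
      sd_ <- apply(Xt[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ < 1e-12] <- 1
      Ztr <- sweep(sweep(Xt[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      Zte <- sweep(sweep(Xt[!tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      fit <- e1071::svm(Ztr, y[tr], kernel = "linear", cost = 1,
                        scale = FALSE)
      pred <- stats::predict(fit, Zte, decision.values = return_decision)
      per_fold[k, tt] <- mean(pred == y[!tr])
      if (return_decision) {
        dv <- attr(pred, "decision.values")
        # e1071 orients decision values by training-set class order; flip so
        # positive always favours class +1
        if (startsWith(colnames(dv)[1], "-1")) dv <- -dv
        decision[!tr, tt] <- as.numeric(dv)
      }
    }
  }
  list(accuracy = colMeans(per_fold), per_fold = per_fold,
       decision = decision, fold = fold)
}

.decoding_result <- function(accuracy, time_s, paradigm, band_hz, n_folds,
                             seed, classifier, per_fold) {
  structure(list(accuracy = accuracy, time_s = time_s, paradigm = paradigm,
                 band_hz = band_hz, n_folds = n_folds, seed = seed,
                 classifier = classifier, per_fold = per_fold),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s%s: %d timepoints, %d-fold CV, mean acc %.3f (peak %.3f)\n",
              x$paradigm,
              if (!is.na(x$band_hz)) sprintf(" @ %g Hz", x$band_hz) else "",
              length(x$accuracy), x$n_folds, mean(x$accuracy), max(x$accuracy)))
  invisible(x)
}

#' Instantaneous (broadband) signal decoding
#'
#' Trains and tests a linear maximum-margin classifier on the raw
#' multichannel values at every timepoint independently, with stratified
#' k-fold cross-validation. Fold structure is shared across timepoints so
#' the accuracy timecourse is comparable point to point; chance level is
#' 0.5. For oscillatory evoked responses the accuracy timecourse inherits
#' the frequency-doubled structure of the class separation.
#'
#' @param dataset a `trial_dataset`.
#' @param n_folds number of CV folds (default 3).
#' @param seed integer seed controlling the fold assignment.
#' @return a `decoding_result` with per-timepoint `accuracy` and
#'   fold-level accuracies.
#' @export
decode_instantaneous <- function(dataset, n_folds = 3, seed = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  r <- .cv_decode_timecourse(dataset$data, dataset$labels, n_folds, seed)
  .decoding_result(r$accuracy, dataset$time_s, "instantaneous", NA_real_,
                   n_folds, seed, "linear_svm_cost1", r$per_fold)
}

#' Narrowband signal decoding of one frequency band
#'
#' Same protocol as [decode_instantaneous()] applied to the real STFT
#' coefficients of one band (P features per timepoint).
#'
#' @param features a `spectral_features` object (carries the labels).
#' @param band_hz band centre frequency.
#' @inheritParams decode_instantaneous
#' @return a `decoding_result`.
#' @export
decode_narrowband <- function(features, band_hz, n_folds = 3, seed = 1) {
  X <- band_real_features(features, band_hz)
  r <- .cv_decode_timecourse(X, features$labels, n_folds, seed)
  .decoding_result(r$accuracy, features$time_s, "narrowband", band_hz,
                   n_folds, seed, "linear_svm_cost1", r$per_fold)
}

#' Complex spectrum decoding of one frequency band
#'
#' Same protocol on the stacked real and imaginary STFT coefficients
#' (2P features per timepoint). On model-matched data its expected
#' accuracy is at least that of [decode_narrowband()]: the extra imaginary
#' features carry the signal-gradient information that stabilises the
#' accuracy timecourse.
#'
#' @inheritParams decode_narrowband
#' @return a `decoding_result`.
#' @export
decode_complex <- function(features, band_hz, n_folds = 3, seed = 1) {
  X <- band_complex_features(features, band_hz)
  r <- .cv_decode_timecourse(X, features$labels, n_folds, seed)
  .decoding_result(r$accuracy, features$time_s, "complex", band_hz,
                   n_folds, seed, "linear_svm_cost1", r$per_fold)
}

#' Aggregate cross-frequency decoding
#'
#' Nested cross-validation stacking the per-band complex-spectrum decoders:
#' the inner loop produces out-of-fold SVM decision values per band and
#' timepoint; the outer loop trains a random-forest ensemble on those
#' band-wise decision values and evaluates it on held-out trials. The
#' outer 2-fold split is repeated `n_repeats` times over resampled
#' stratified partitions, and accuracies are averaged, estimating the
#' aggregate information distributed over all frequency bands.
#'
#' @param features a `spectral_features` object.
#' @param bands_hz bands to aggregate (default: all bands).
#' @param n_folds_outer outer folds (default 2).
#' @param n_trees random-forest trees (default 100).
#' @param n_repeats outer-loop repetitions (default 10).
#' @param n_folds_inner inner CV folds for the band decoders (default 3).
#' @param seed integer seed.
#' @return a `decoding_result` with paradigm `"aggregate"`.
#' @export
decode_aggregate <- function(features, bands_hz = features$band_hz,
                             n_folds_outer = 2, n_trees = 100,
                             n_repeats = 10, n_folds_inner = 3, seed = 1) {
  stopifnot(inherits(features, "spectral_features"))
  if (n_folds_outer < 2) stop("need at least 2 outer folds")
  labels <- features$labels
  N <- length(labels)
  Tn <- dim(features$coeffs)[4]
  nb <- length(bands_hz)

  # inner loop: out-of-fold decision values per band, per trial, per time
  dec <- array(NA_real_, dim = c(N, nb, Tn))
  for (j in seq_len(nb)) {
    X <- band_complex_features(features, bands_hz[j])
    r <- .cv_decode_timecourse(X, labels, n_folds_inner, seed + j,
                               return_decision = TRUE)
    dec[, j, ] <- r$decision
  }

  y <- factor(labels, levels = c(-1, 1))
  acc_rep <- matrix(NA_real_, n_repeats, Tn)
  for (rep_i in seq_len(n_repeats)) {
    fold <- .stratified_folds(labels, n_folds_outer, seed + 1000L * rep_i)
    fold_acc <- matrix(NA_real_, n_folds_outer, Tn)
    for (k in seq_len(n_folds_outer)) {
      tr <- fold != k
      for (tt in seq_len(Tn)) {
        Ftr <- dec[tr, , tt, drop = FALSE]; dim(Ftr) <- c(sum(tr), nb)
        Fte <- dec[!tr, , tt, drop = FALSE]; dim(Fte) <- c(sum(!tr), nb)
        set.seed(seed + 7L * rep_i + 13L * k + 17L * tt)
        rf <- randomForest::randomForest(Ftr, y[tr], ntree = n_trees)
        fold_acc[k, tt] <- mean(stats::predict(rf, Fte) == y[!tr])
      }
    }
    acc_rep[rep_i, ] <- colMeans(fold_acc)
  }
  .decoding_result(colMeans(acc_rep), features$time_s, "aggregate",
                   NA_real_, n_folds_outer, seed,
                   sprintf("rf%d_over_linear_svm", n_trees), acc_rep)
}

#' Mass pairwise decoding over multiple conditions
#'
#' Runs the chosen paradigm on every pair of condition labels (relabelled
#' +1/-1) and aggregates by the mean accuracy over pairs — the mass
#' pairwise classification protocol used for multi-stimulus designs.
#'
#' @param data a `trial_dataset` whose `meta$condition` (or the `conditions`
#'   argument) gives a per-trial condition id with 2 or more levels.
#' @param conditions optional per-trial condition vector overriding
#'   `data$meta$condition`.
#' @param paradigm `"instantaneous"`, `"narrowband"`, or `"complex"`.
#' @param band_hz band for the narrowband/complex paradigms.
#' @param window_ms STFT window for the narrowband/complex paradigms.
#' @param n_folds,seed CV parameters passed through.
#' @return list with `pairs` (per-pair `decoding_result`s, named "a|b"),
#'   `mean_accuracy` (timecourse averaged over pairs), `skipped` (pairs
#'   with too few trials).
#' @export
pairwise_decode <- function(data, conditions = NULL,
                            paradigm = c("instantaneous", "narrowband", "complex"),
                            band_hz = NULL, window_ms = 100,
                            n_folds = 3, seed = 1) {
  paradigm <- match.arg(paradigm)
  stopifnot(inherits(data, "trial_dataset"))
  if (is.null(conditions)) conditions <- data$meta$condition
  if (is.null(conditions)) stop("no per-trial condition ids supplied")
  if (length(conditions) != dim(data$data)[1])
    stop("conditions length does not match the number of trials")
  lev <- sort(unique(conditions))
  if (length(lev) < 2) stop("need at least 2 condition labels")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  results <- list(); skipped <- character(0)
  for (pr in pairs) {
    key <- paste(pr, collapse = "|")
    sel <- conditions %in% pr
    lab <- ifelse(conditions[sel] == pr[1], 1L, -1L)
    if (min(table(lab)) < 2 * n_folds) {
      warning("skipping pair ", key, ": too few trials")
      skipped <- c(skipped, key)
      next
    }
    ds <- trial_dataset(data$data[sel, , , drop = FALSE], lab,
                        data$sample_rate_hz, data$time_s,
                        meta = list(pair = pr))
    results[[key]] <- switch(paradigm,
      instantaneous = decode_instantaneous(ds, n_folds, seed),
      narrowband = decode_narrowband(stft_epochs(ds, window_ms), band_hz,
                                     n_folds, seed),
      complex = decode_complex(stft_epochs(ds, window_ms), band_hz,
                               n_folds, seed))
  }
  if (!length(results)) stop("no decodable pairs")
  acc <- rowMeans(sapply(results, function(r) r$accuracy))
  list(pairs = results, mean_accuracy = acc,
       time_s = results[[1]]$time_s, skipped = skipped)
}

#' Power spectrum of a decoding-accuracy timecourse
#'
#' Mean-removed periodogram of the accuracy timecourse, used to detect
#' frequency-doubled harmonics and representational-aliasing peaks in
#' empirical decoding output.
#'
#' @param result a `decoding_result` (needs at least 8 timepoints).
#' @return data frame with `freq_hz`, `power`.
#' @export
accuracy_psd <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  if (length(result$accuracy) < 8) stop("accuracy timecourse too short")
  fs <- 1 / stats::median(diff(result$time_s))
  spectrum_table(result$accuracy, fs)
}

#' Cluster-based permutation test for paired timecourses
#'
#' Paired-difference t statistic per timepoint; temporal clusters are runs
#' of contiguous same-sign statistics exceeding the two-sided
#' `cluster_alpha` t threshold, with mass the summed t values. The null
#' distribution of the maximum absolute cluster mass is built by randomly
#' sign-flipping each unit's difference timecourse, giving family-wise
#' error control over time.
#'
#' @param cond_a,cond_b units x time matrices of paired timecourses
#'   (units = subjects or simulation seeds; at least 5).
#' @param n_permutations number of sign-flip permutations (at least 500).
#' @param cluster_alpha cluster-forming two-sided alpha (default 0.05).
#' @param seed integer seed.
#' @return a `cluster_test_result`: `cluster_spans` (list of time-index
#'   ranges), `cluster_masses`, `p_values` (each at least
#'   `1/(n_permutations + 1)`), `threshold`, `n_permutations`, `t_obs`.
#' @export
cluster_permutation_test <- function(cond_a, cond_b, n_permutations = 1000,
                                     cluster_alpha = 0.05, seed = 1) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  if (!all(dim(cond_a) == dim(cond_b)))
    stop("cond_a and cond_b must have matching unit and time dimensions")
  n <- nrow(cond_a)
  if (n < 5) stop("need at least 5 paired units")
  if (n_permutations < 500) stop("need at least 500 permutations")
  D <- cond_a - cond_b
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  tstat <- function(M) {
    mu <- colMeans(M)
    se <- sqrt(pmax(colMeans(M^2) - mu^2, 0) * n / (n - 1) / n)
    se[se < 1e-300] <- 1e-300
    mu / se
  }
  clusters_of <- function(tv) {
    above <- abs(tv) > thr
    sgn <- sign(tv)
    out <- list()
    i <- 1
    while (i <= length(tv)) {
      if (above[i]) {
        j <- i
        while (j < length(tv) && above[j + 1] && sgn[j + 1] == sgn[i]) j <- j + 1
        out[[length(out) + 1]] <- list(span = c(i, j), mass = sum(tv[i:j]))
        i <- j + 1
      } else i <- i + 1
    }
    out
  }

  t_obs <- tstat(D)
  obs <- clusters_of(t_obs)
  set.seed(seed)
  max_null <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    tp <- tstat(D * fl)
    cl <- clusters_of(tp)
    max_null[p] <- if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass")))
                   else 0
  }
  masses <- vapply(obs, `[[`, numeric(1), "mass")
  pvals <- vapply(masses, function(m)
    (1 + sum(max_null >= abs(m))) / (n_permutations + 1), numeric(1))
  structure(list(
    cluster_spans = lapply(obs, `[[`, "span"),
    cluster_masses = masses,
    p_values = pvals,
    n_permutations = as.integer(n_permutations),
    threshold = thr,
    t_obs = t_obs
  ), class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), threshold |t| > %.3f, %d permutations\n",
              length(x$cluster_masses), x$threshold, x$n_permutations))
  for (i in seq_along(x$cluster_masses))
    cat(sprintf("  [%d..%d] mass %.2f  p = %.4f\n",
                x$cluster_spans[[i]][1], x$cluster_spans[[i]][2],
                x$cluster_masses[i], x$p_values[i]))
  invisible(x)
}
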