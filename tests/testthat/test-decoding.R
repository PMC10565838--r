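test_that("exchangeable classes decode at chance and inputs are validated", {
  # average over several independent null simulations at one timepoint so
  # the binomial CI applies to (nearly) independent draws
  accs <- sapply(1:8, function(s) {
    ds <- simulate_trials(null_model(epoch_s = 0.1), 60, seed = 100 + s)
    decode_instantaneous(ds, seed = s)$accuracy[5]
  })
  n_eff <- 8 * 60
  expect_lt(abs(mean(accs) - 0.5), 2.576 * sqrt(0.25 / n_eff))

  ds <- simulate_trials(null_model(), 12, seed = 1)
  ds$labels <- rep(1L, 12)
  expect_error(decode_instantaneous(ds), "both classes")
})

test_that("separable noise-free-limit data decodes perfectly at separation peaks", {
  m <- model_example1(amplitude = 1, noise_sd = 1e-4)
  ds <- simulate_trials(m, 24, seed = 2)
  res <- decode_instantaneous(ds, seed = 2)
  # separation peaks at t = 0, 0.05, 0.10, ... (cos^2 maxima)
  peak_idx <- which(ds$time_s %in% c(0, 0.05, 0.1))
  expect_equal(res$accuracy[peak_idx], rep(1, 3))
  expect_equal(colMeans(res$per_fold), res$accuracy, tolerance = 1e-12)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("instantaneous accuracy timecourse oscillates at twice the evoked frequency", {
  m <- model_example1(amplitude = 1.2)
  ds <- simulate_trials(m, 300, seed = 3)
  res <- decode_instantaneous(ds, seed = 3)
  psd <- accuracy_psd(res)
  nz <- psd[psd$freq_hz > 0, ]
  expect_equal(nz$freq_hz[which.max(nz$power)], 20)
})

test_that("decoding runs are exactly reproducible from their seed", {
  ds <- simulate_trials(model_example1(), 60, seed = 4)
  a <- decode_instantaneous(ds, seed = 9)
  b <- decode_instantaneous(ds, seed = 9)
  expect_identical(a$accuracy, b$accuracy)
  sf <- stft_epochs(ds)
  expect_identical(decode_complex(sf, 10, seed = 9)$accuracy,
                   decode_complex(sf, 10, seed = 9)$accuracy)
})

test_that("narrowband and complex paradigms coincide at 0 Hz and complex dominates at 10 Hz", {
  m <- model_example1()
  ds <- simulate_trials(m, 160, seed = 5)
  sf <- stft_epochs(ds, window_ms = 100)
  # 0 Hz: imaginary features are identically zero, same feature space
  n0 <- decode_narrowband(sf, 0, seed = 7)
  c0 <- decode_complex(sf, 0, seed = 7)
  expect_equal(n0$accuracy, c0$accuracy, tolerance = 1e-12)
  # 10 Hz: complex accuracy sits near the envelope of the narrowband one
  n10 <- decode_narrowband(sf, 10, seed = 7)
  c10 <- decode_complex(sf, 10, seed = 7)
  expect_gt(mean(c10$accuracy), mean(n10$accuracy))
  # null data: both at chance (loose bound, one seed)
  ds0 <- simulate_trials(null_model(), 80, seed = 6)
  sf0 <- stft_epochs(ds0)
  expect_lt(abs(mean(decode_narrowband(sf0, 10, seed = 8)$accuracy) - 0.5),
            0.1)
})

# model in which three bands carry information on different channels, so
# the per-band complex decoders have complementary information
three_band_model <- function() {
  evoked_spectrum_model(
    3, 100, 0.2, freqs_hz = c(10, 20, 30), amplitudes = diag(3),
    noise_cov = replicate(3, diag(3), simplify = FALSE))
}

test_that("aggregate decoding matches a lone informative band and exploits complementary bands", {
  # one informative band: aggregating over {10, 30} adds nothing
  m1 <- evoked_spectrum_model(2, 100, 0.3, freqs_hz = c(10, 30),
                              amplitudes = matrix(c(1, 1, 0, 0), 2, 2,
                                                  byrow = TRUE),
                              noise_cov = list(diag(2), diag(2)))
  ds1 <- simulate_trials(m1, 160, seed = 11)
  sf1 <- stft_epochs(ds1, window_ms = 100)
  agg1 <- decode_aggregate(sf1, bands_hz = c(10, 30), n_repeats = 3,
                           n_trees = 60, seed = 11)
  single <- decode_complex(sf1, 10, seed = 11)
  expect_lt(abs(mean(agg1$accuracy) - mean(single$accuracy)), 0.06)

  # complementary bands: aggregate exceeds the best single band
  # (paired one-sided test over seeds)
  diffs <- sapply(1:6, function(s) {
    ds <- simulate_trials(three_band_model(), 240, seed = 20 + s)
    sf <- stft_epochs(ds, window_ms = 100)
    agg <- decode_aggregate(sf, bands_hz = c(10, 20, 30), n_repeats = 4,
                            n_trees = 100, seed = s)
    best <- max(sapply(c(10, 20, 30), function(b)
      mean(decode_complex(sf, b, seed = s)$accuracy)))
    mean(agg$accuracy) - best
  })
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)

  # null data: chance
  ds0 <- simulate_trials(null_model(epoch_s = 0.2), 80, seed = 31)
  sf0 <- stft_epochs(ds0, window_ms = 100)
  agg0 <- decode_aggregate(sf0, bands_hz = c(10, 20), n_repeats = 2,
                           n_trees = 40, seed = 31)
  expect_lt(abs(mean(agg0$accuracy) - 0.5), 0.12)
})

test_that("mass pairwise decoding enumerates pairs and orders them by separation", {
  # 4 conditions with graded DC offsets on channel 1
  set.seed(41)
  offs <- c(0, 0.6, 1.5, 3.5)
  n_per <- 60; Tn <- 10
  cond <- rep(1:4, each = n_per)
  x <- array(stats::rnorm(4 * n_per * 2 * Tn), dim = c(4 * n_per, 2, Tn))
  x[, 1, ] <- x[, 1, ] + offs[cond]
  ds <- trial_dataset(x, rep(c(1L, -1L), length.out = 4 * n_per), 100,
                      meta = list(condition = cond))
  res <- pairwise_decode(ds, paradigm = "instantaneous", seed = 42)
  expect_length(res$pairs, 6)
  expect_named(res$pairs, c("1|2", "1|3", "1|4", "2|3", "2|4", "3|4"))
  acc <- sapply(res$pairs, function(r) mean(r$accuracy))
  sep <- utils::combn(offs, 2, function(v) abs(diff(v)))
  # accuracies ordered by the true mean separations
  expect_equal(order(acc), order(sep))
  # mean over pairs matches the reported aggregate
  expect_equal(res$mean_accuracy,
               rowMeans(sapply(res$pairs, `[[`, "accuracy")))

  # 2 conditions: identical to a direct two-class decode
  ds2 <- simulate_trials(model_example1(epoch_length_s = 0.1), 80, seed = 43)
  ds2$meta$condition <- ifelse(ds2$labels == 1, "a", "b")
  direct <- decode_instantaneous(ds2, seed = 44)
  via_pairs <- pairwise_decode(ds2, paradigm = "instantaneous", seed = 44)
  expect_length(via_pairs$pairs, 1)
  expect_equal(via_pairs$pairs[[1]]$accuracy, direct$accuracy)
})

test_that("accuracy spectra expose planted oscillations and reject short input", {
  fs <- 100
  t <- (0:49) / fs
  res <- structure(list(accuracy = 0.7 + 0.1 * cos(2 * pi * 20 * t),
                        time_s = t, paradigm = "instantaneous",
                        band_hz = NA, n_folds = 3, seed = 1,
                        classifier = "x", per_fold = NULL),
                   class = "decoding_result")
  psd <- accuracy_psd(res)
  nz <- psd[psd$freq_hz > 0, ]
  expect_equal(nz$freq_hz[which.max(nz$power)], 20)
  # constant accuracy: nothing left after mean removal
  res$accuracy <- rep(0.8, 50)
  expect_lt(max(accuracy_psd(res)$power), 1e-20)
  res$accuracy <- res$accuracy[1:5]; res$time_s <- t[1:5]
  expect_error(accuracy_psd(res), "short")
})

test_that("cluster permutation test finds planted effects and nothing in null data", {
  set.seed(51)
  # enough units that re-drawing the identity sign pattern (which would tie
  # with the observed mass) is vanishingly unlikely in 500 permutations
  n_units <- 20; Tn <- 40
  base <- matrix(stats::rnorm(n_units * Tn, sd = 0.3), n_units, Tn)
  # identical inputs: no clusters at all
  r0 <- cluster_permutation_test(base, base, n_permutations = 500, seed = 1)
  expect_length(r0$cluster_masses, 0)

  # large localized difference: cluster covers the true interval at the
  # smallest achievable p-value
  eff <- matrix(stats::rnorm(n_units * Tn, sd = 0.3), n_units, Tn)
  eff[, 16:24] <- eff[, 16:24] + 1
  r1 <- cluster_permutation_test(eff, base, n_permutations = 500, seed = 2)
  main <- which.max(abs(r1$cluster_masses))
  expect_equal(r1$p_values[main], 1 / 501)
  expect_lte(r1$cluster_spans[[main]][1], 16)
  expect_gte(r1$cluster_spans[[main]][2], 24)
  expect_true(all(r1$p_values >= 1 / 501))

  expect_error(cluster_permutation_test(base, base[1:4, ], 500), "matching")
  expect_error(cluster_permutation_test(base[1:3, ], base[1:3, ], 500),
               "at least 5")
  expect_error(cluster_permutation_test(base, base, n_permutations = 100),
               "500")
})
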