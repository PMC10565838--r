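test_that("narrowband separation expansion matches the brute-force Mahalanobis oracle", {
  # hand-derivable case: one channel, amplitude a, phase 0, unit variance
  # d^2(t) = 4 a^2 cos^2(wt) = 2a^2 + 2a^2 cos(2wt)
  m1 <- evoked_spectrum_model(1, 100, 0.5, freqs_hz = 10, amplitudes = 0.7,
                              phases = 0, noise_cov = diag(1))
  sp <- separation_params(m1, 10)
  expect_equal(sp$c, 2 * 0.7^2)
  expect_equal(sp$r, 2 * 0.7^2)
  expect_equal(sp$terms$freq_hz, 20)

  # zero amplitude in band: c = r = 0
  m0 <- evoked_spectrum_model(2, 100, 0.5, freqs_hz = 10, amplitudes = 0)
  sp0 <- separation_params(m0, 10)
  expect_equal(c(sp0$c, sp0$r), c(0, 0))

  # random multichannel models against direct evaluation at 1000 timepoints
  tg <- seq(0, 1, length.out = 1000)
  for (seed in 1:5) {
    m <- rand_model(seed, n_channels = 3, n_bands = 1)
    f <- m$freqs_hz[1]
    sp <- separation_params(m, f)
    expect_lt(max(abs(eval_separation(sp, tg) -
                      direct_band_separation(m, f, tg))), 1e-10)
    expect_lte(sp$r, sp$c + 1e-12)  # separation never negative
  }
  expect_error(separation_params(m1, 11), "not one of")
})

test_that("broadband expansion produces the pairwise harmonic set bounded by 2 Omega", {
  # single band: degenerates to the narrowband constants
  m1 <- rand_model(7, n_bands = 1)
  f <- m1$freqs_hz[1]
  nb <- separation_params(m1, f)
  bb <- broadband_separation(m1)
  expect_equal(bb$c, nb$c)
  expect_equal(bb$terms$r, nb$terms$r)
  expect_equal(bb$max_freq_hz, 2 * f)

  # components at 10 and 15 Hz: harmonics {5, 20, 25, 30}, maximum 30
  m2 <- model_example2()
  bb2 <- broadband_separation(m2)
  expect_equal(sort(bb2$terms$freq_hz), c(5, 20, 25, 30))
  expect_equal(bb2$max_freq_hz, 30)

  # random 2-band models against brute force
  tg <- seq(0, 1, length.out = 1000)
  for (seed in 11:15) {
    m <- rand_model(seed, n_channels = 3, n_bands = 2)
    bb <- broadband_separation(m)
    expect_lt(max(abs(eval_separation(bb, tg) -
                      direct_broadband_separation(m, tg))), 1e-10)
    expect_lte(bb$max_freq_hz, 2 * max(m$freqs_hz) + 1e-9)
  }
})

test_that("link functions have the exact endpoints and verified interior values", {
  expect_equal(link_mi(0), 0)
  expect_gt(link_mi(1e4), 1 - 1e-6)      # 1-bit ceiling for binary labels
  expect_equal(link_accuracy(0), 0.5)
  expect_gt(link_accuracy(1e4), 1 - 1e-9)
  expect_error(link_mi(-1), "non-negative")
  expect_error(link_accuracy(-1), "non-negative")
  expect_error(link_distance(-0.5), "non-negative")

  # Monte-Carlo oracle for the MI link at separation 4, via a DC-contrast
  # model (mean difference 2, unit variance)
  mdc <- evoked_spectrum_model(1, 100, 0.5, freqs_hz = 0, amplitudes = 1,
                               phases = 0, noise_cov = diag(1))
  mc <- mc_mi_estimate(mdc, 0, "narrowband", 0, n_samples = 1e6, seed = 3)
  expect_lt(abs(link_mi(4) - mc$estimate), 3 * mc$se)

  # empirical Bayes-rule accuracy at separation 1: classify x ~ N(+-d/2, 1)
  # by sign, accuracy should be Phi(d/2)
  set.seed(4)
  n <- 1e6
  y <- rep(c(1, -1), n / 2)
  x <- stats::rnorm(n, mean = y * 0.5)
  emp <- mean(sign(x) == y)
  expect_lt(abs(link_accuracy(1) - emp), 3 * sqrt(emp * (1 - emp) / n))
})

test_that("link_mi is monotone and concave; all links monotone", {
  s <- seq(0, 25, by = 0.25)
  v <- link_mi(s)
  expect_true(all(diff(v) > 0))
  expect_true(all(diff(diff(v)) < 1e-10))  # concavity by finite differences
  expect_true(all(diff(link_accuracy(s)) > 0))
  expect_true(all(diff(link_distance(s)) > 0))
})

test_that("narrowband information oscillates at exactly twice the band frequency", {
  # frequency-doubled dominant peak, checked on an FFT bin grid
  m <- model_example1()
  tg <- seq(0, 1 - 1 / 400, by = 1 / 400)
  tc <- narrowband_info_timecourse(m, 10, time_s = tg)
  expect_equal(dominant_frequency(tc$value, 400), 20)

  # single nonzero-frequency peak at exactly 2w: all other bins tiny
  sp <- spectrum_table(tc$value - mean(tc$value), 400)
  nz <- sp[sp$freq_hz > 0, ]
  main <- nz$power[nz$freq_hz == 20]
  # concave link generates small harmonics of 20 Hz but no other lines
  others <- nz$power[abs(nz$freq_hz %% 20) > 1e-9]
  expect_lt(max(others) / main, 1e-20)

  # zero amplitudes: flat zero
  tc0 <- narrowband_info_timecourse(null_model(), 10)
  expect_equal(tc0$value, rep(0, length(tc0$value)))

  # composition oracle: pointwise equal to link(direct separation)
  for (seed in 21:23) {
    mm <- rand_model(seed, n_bands = 1)
    f <- mm$freqs_hz[1]
    tc <- narrowband_info_timecourse(mm, f)
    expect_equal(tc$value, link_mi(direct_band_separation(mm, f, mm$time_s)),
                 tolerance = 1e-8)
  }
})

test_that("broadband information matches narrowband for one band and the MC oracle for two", {
  m1 <- rand_model(31, n_bands = 1)
  expect_equal(broadband_info_timecourse(m1)$value,
               narrowband_info_timecourse(m1, m1$freqs_hz[1])$value,
               tolerance = 1e-12)

  m2 <- rand_model(32, n_bands = 2)
  probes <- c(0.05, 0.21, 0.33)
  an <- broadband_info_timecourse(m2, time_s = probes)$value
  for (i in seq_along(probes)) {
    mc <- mc_mi_estimate(m2, probes[i], "broadband", n_samples = 1e5,
                         seed = 100 + i)
    expect_lt(abs(an[i] - mc$estimate), 3 * mc$se)
  }
})

test_that("complex-spectrum information is constant, equals link(2c), and dominates the narrowband peak", {
  m <- model_example1()
  cx <- complex_info_timecourse(m, 10)
  expect_equal(stats::var(cx$value), 0)
  sp <- separation_params(m, 10)
  expect_equal(cx$value[1], link_mi(2 * sp$c))

  # equality with the narrowband maximum when r = c (single-phase model)
  nb <- narrowband_info_timecourse(m, 10)
  expect_equal(sp$r, sp$c)
  expect_equal(cx$value[1], max(nb$value), tolerance = 1e-6)

  # strict dominance otherwise, over random models
  for (seed in 41:60) {
    mm <- rand_model(seed, n_bands = 1)
    f <- mm$freqs_hz[1]
    spm <- separation_params(mm, f)
    cxv <- complex_info_timecourse(mm, f)$value[1]
    nbm <- max(narrowband_info_timecourse(mm, f)$value)
    expect_gte(cxv, nbm - 1e-10)
    if (spm$r < spm$c - 1e-6) expect_gt(cxv, nbm)
  }

  expect_equal(complex_info_timecourse(null_model(), 10)$value,
               rep(0, null_model()$n_time))
})

test_that("Monte-Carlo estimates vanish at exchangeable conditions and separation troughs", {
  mc0 <- mc_mi_estimate(null_model(), 0.1, "broadband", n_samples = 1e4,
                        seed = 5)
  expect_lt(abs(mc0$estimate), 3 * mc0$se + 1e-3)

  # one-channel-style trough: c = r so d^2 = 0 when cos(2wt + xi) = -1;
  # for the 10 Hz zero-phase model that is t = 1/40 s
  m <- model_example1()
  mc_tr <- mc_mi_estimate(m, 1 / 40, "narrowband", 10, n_samples = 1e4,
                          seed = 6)
  expect_lt(abs(mc_tr$estimate), 3 * mc_tr$se + 1e-3)

  # complex scope is time-invariant: two distant timepoints agree
  a <- mc_mi_estimate(m, 0.07, "complex", 10, n_samples = 1e5, seed = 7)
  b <- mc_mi_estimate(m, 0.41, "complex", 10, n_samples = 1e5, seed = 8)
  expect_lt(abs(a$estimate - b$estimate), 3 * sqrt(a$se^2 + b$se^2))

  expect_error(mc_mi_estimate(m, 0, "wavelet", 10), "scope")
  expect_error(mc_mi_estimate(m, 0, "broadband", n_samples = 100), "1e4")
})

test_that("induced-effect probes show time-invariance and subadditivity", {
  # equal scalings and no evoked contrast: zero information
  m_null <- evoked_spectrum_model(2, 100, 0.5, freqs_hz = 10, amplitudes = 0,
                                  noise_cov = diag(2),
                                  induced = matrix(c(1, 1), 1, 2))
  p0 <- induced_info_probe(m_null, 0.1, "narrowband", 10, n_samples = 1e4,
                           seed = 9)
  expect_lt(abs(p0$estimate), 3 * p0$se + 1e-3)

  # induced-only contrast: constant over time (timepoints half a period apart)
  m_ind <- evoked_spectrum_model(2, 100, 0.5, freqs_hz = 10, amplitudes = 0,
                                 noise_cov = diag(2),
                                 induced = matrix(c(1.8, 1), 1, 2))
  pa <- induced_info_probe(m_ind, 0.10, "narrowband", 10, n_samples = 1e5,
                           seed = 10)
  pb <- induced_info_probe(m_ind, 0.15, "narrowband", 10, n_samples = 1e5,
                           seed = 11)
  expect_lt(abs(pa$estimate - pb$estimate), 3 * sqrt(pa$se^2 + pb$se^2))

  # evoked + induced never exceeds the sum of the separate effects
  m_both <- evoked_spectrum_model(2, 100, 0.5, freqs_hz = 10, amplitudes = 0.6,
                                  noise_cov = diag(2),
                                  induced = matrix(c(1.8, 1), 1, 2))
  m_ev <- evoked_spectrum_model(2, 100, 0.5, freqs_hz = 10, amplitudes = 0.6,
                                noise_cov = diag(2))
  for (tt in c(0.03, 0.1, 0.22)) {
    both <- induced_info_probe(m_both, tt, "narrowband", 10, n_samples = 1e5,
                               seed = 12)
    ind <- induced_info_probe(m_ind, tt, "narrowband", 10, n_samples = 1e5,
                              seed = 13)
    ev <- mc_mi_estimate(m_ev, tt, "narrowband", 10, n_samples = 1e5,
                         seed = 14)
    tol <- 3 * sqrt(both$se^2 + ind$se^2 + ev$se^2)
    expect_lte(both$estimate, ev$estimate + ind$estimate + tol)
  }
  expect_error(induced_info_probe(m_ev, 0, "narrowband", 10), "induced")
})
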