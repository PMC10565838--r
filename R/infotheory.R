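#' Sinusoidal expansion of the narrowband class separation
#'
#' Expands the squared Mahalanobis distance between the two class means of
#' one frequency band into its sinusoidal form. With class-mean difference
#' `m(t) = 2 A cos(w t + phi)` (vector over channels) and band noise
#' covariance Sigma, the product-to-sum identity gives
#' \deqn{d^2(t) = m(t)' \Sigma^{-1} m(t) = c + r \cos(2 \omega t + \xi),}
#' i.e. the separation — and hence every monotone information metric of it —
#' oscillates at exactly twice the component frequency. Writing
#' `u_j = a_j exp(i phi_j)`, the constants are `c = 2 Re(u^H S u)` and
#' `r exp(i xi) = 2 u^T S u` with `S = Sigma^{-1}`.
#'
#' @param model an [evoked_spectrum_model()].
#' @param band_hz one of the model's component frequencies.
#' @return a `separation_params` object with fields `c`, `r`, `xi`,
#'   `band_hz`, and a `terms` table (`freq_hz`, `r`, `xi`) so that
#'   `d^2(t) = c + sum r_k cos(2 pi f_k t + xi_k)`. The invariant `r <= c`
#'   always holds (the separation is non-negative).
#' @export
separation_params <- function(model, band_hz) {
  b <- .band_index(model, band_hz)
  S <- solve(model$noise_cov[[b]])
  u <- model$amplitudes[b, ] * exp(1i * model$phases[b, ])
  cc <- 2 * Re(Conj(u) %*% S %*% u)[1]
  rho <- 2 * (t(u) %*% S %*% u)[1]
  r <- Mod(rho)
  xi <- if (r > 0) Arg(rho) %% (2 * pi) else 0
  terms <- if (r > 0) data.frame(freq_hz = 2 * band_hz, r = r, xi = xi)
           else data.frame(freq_hz = numeric(0), r = numeric(0), xi = numeric(0))
  structure(list(scope = "narrowband", band_hz = band_hz,
                 c = cc, r = r, xi = xi, terms = terms,
                 max_freq_hz = if (r > 0) 2 * band_hz else 0),
            class = "separation_params")
}

.band_index <- function(model, band_hz) {
  stopifnot(inherits(model, "evoked_spectrum_model"))
  b <- which(abs(model$freqs_hz - band_hz) < 1e-9)
  if (length(b) != 1)
    stop(sprintf("band %g Hz is not one of the model's frequencies (%s)",
                 band_hz, paste(model$freqs_hz, collapse = ", ")))
  b
}

#' Sinusoidal expansion of the broadband class separation
#'
#' The broadband signal sums all bands, so the class-mean difference is
#' `m(t) = sum_w 2 A_w cos(w t + phi_w)` and the noise covariance is the
#' band sum. Expanding `m(t)' S m(t)` produces a DC constant plus sinusoids
#' at every pairwise sum and difference frequency `w_a + w_b` and
#' `|w_a - w_b|` — including the doubled frequencies `2w` — so the maximum
#' harmonic equals twice the highest component frequency (2 Omega).
#'
#' @param model an [evoked_spectrum_model()] with at least one band.
#' @return a `separation_params` with fields `c` (DC term) and `terms`
#'   (one row per nonzero harmonic: `freq_hz`, `r`, `xi`).
#' @export
broadband_separation <- function(model) {
  stopifnot(inherits(model, "evoked_spectrum_model"))
  nb <- length(model$freqs_hz)
  if (nb < 1) stop("model has no frequency bands")
  Sigma <- Reduce(`+`, model$noise_cov)
  S <- tryCatch(solve(Sigma), error = function(e)
    stop("summed noise covariance is singular"))
  U <- lapply(seq_len(nb), function(b)
    model$amplitudes[b, ] * exp(1i * model$phases[b, ]))

  acc <- new.env()
  add_term <- function(freq, amp) {
    # d^2 contribution Re(amp * exp(i 2 pi freq t)); negative freqs folded
    if (freq < 0) { freq <- -freq; amp <- Conj(amp) }
    key <- sprintf("%.9f", freq)
    prev <- if (is.null(acc[[key]])) 0 + 0i else acc[[key]]
    acc[[key]] <- prev + amp
  }
  for (a in seq_len(nb)) {
    for (b in seq_len(nb)) {
      fa <- model$freqs_hz[a]; fb <- model$freqs_hz[b]
      ua <- U[[a]]; ub <- U[[b]]
      # 4 cosvec_a' S cosvec_b = 2 Re(h_diff e^{i(wa-wb)t}) + 2 Re(h_sum e^{i(wa+wb)t})
      add_term(fa - fb, 2 * (t(ua) %*% S %*% Conj(ub))[1])
      add_term(fa + fb, 2 * (t(ua) %*% S %*% ub)[1])
    }
  }
  keys <- ls(acc)
  freqs <- as.numeric(keys)
  amps <- vapply(keys, function(k) acc[[k]], complex(1))
  ord <- order(freqs)
  freqs <- freqs[ord]
  amps <- amps[ord]
  is_dc <- freqs < 1e-9
  c_dc <- sum(Re(amps[is_dc]))
  f_ac <- freqs[!is_dc]
  a_ac <- amps[!is_dc]
  r <- Mod(a_ac)
  keep <- r > 1e-12 * max(c_dc, r, 1e-300)
  terms <- data.frame(freq_hz = f_ac[keep], r = r[keep],
                      xi = Arg(a_ac[keep]) %% (2 * pi))
  structure(list(scope = "broadband", band_hz = NA_real_,
                 c = c_dc, r = if (nrow(terms)) max(terms$r) else 0,
                 xi = NA_real_, terms = terms,
                 max_freq_hz = if (nrow(terms)) max(terms$freq_hz) else 0),
            class = "separation_params")
}

#' Evaluate a separation expansion on a time grid
#'
#' @param params a `separation_params`.
#' @param time_s numeric vector of times (seconds).
#' @return the squared Mahalanobis separation `d^2(t)` at each time.
#' @export
eval_separation <- function(params, time_s) {
  stopifnot(inherits(params, "separation_params"))
  out <- rep(params$c, length(time_s))
  for (k in seq_len(nrow(params$terms))) {
    out <- out + params$terms$r[k] *
      cos(2 * pi * params$terms$freq_hz[k] * time_s + params$terms$xi[k])
  }
  out
}

#' @export
print.separation_params <- function(x, ...) {
  cat(sprintf("<separation_params> scope=%s  c=%.4g  max harmonic=%g Hz\n",
              x$scope, x$c, x$max_freq_hz))
  if (nrow(x$terms)) print(x$terms, row.names = FALSE)
  invisible(x)
}

# ---- link functions: separation -> information metric ----------------------

#' Mutual information of two equiprobable Gaussian classes
#'
#' For binary equiprobable labels and Gaussian class conditionals at squared
#' Mahalanobis distance `separation_sq`, all information about the label
#' lives on the 1-D discriminant projection, where the classes are
#' `N(+d/2, 1)` and `N(-d/2, 1)` with `d = sqrt(separation_sq)`. The mutual
#' information in bits is
#' `1 - E_x[H_2(sigma(d x))]` with `H_2` the binary entropy and `sigma` the
#' logistic function, computed by adaptive quadrature (absolute tolerance
#' 1e-8). Monotone increasing and concave in the separation, 0 at 0 and
#' saturating at 1 bit.
#'
#' @param separation_sq non-negative squared Mahalanobis separation(s).
#' @return mutual information in bits, in `[0, 1]`.
#' @export
link_mi <- function(separation_sq) {
  if (any(separation_sq < 0)) stop("separation_sq must be non-negative")
  vapply(separation_sq, .link_mi_scalar, numeric(1))
}

.link_mi_scalar <- function(s2) {
  if (s2 == 0) return(0)
  d <- sqrt(s2)
  # conditional entropy H(Y|X) under the mixture, in bits
  h2 <- function(p) {
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  integrand <- function(x) {
    mix <- 0.5 * (stats::dnorm(x, -d / 2) + stats::dnorm(x, d / 2))
    p1 <- stats::plogis(d * x)
    mix * h2(p1)
  }
  hcond <- stats::integrate(integrand, -Inf, Inf, abs.tol = 1e-10,
                            rel.tol = 1e-10)$value
  max(0, min(1, 1 - hcond))
}

#' Bayes classification accuracy of two equiprobable Gaussian classes
#'
#' `Phi(sqrt(separation_sq) / 2)`: the accuracy of the optimal linear rule.
#'
#' @inheritParams link_mi
#' @return accuracy in `[0.5, 1]`.
#' @export
link_accuracy <- function(separation_sq) {
  if (any(separation_sq < 0)) stop("separation_sq must be non-negative")
  stats::pnorm(sqrt(separation_sq) / 2)
}

#' Expected absolute standardized discriminant projection
#'
#' The mean absolute value of the standardized projection onto the
#' discriminant direction (a folded normal with mean `d/2`, unit variance):
#' `2 dnorm(d/2) + (d/2) (2 pnorm(d/2) - 1)`. Monotone in the separation;
#' the "distance from the hyperplane" analogue of the other link functions.
#'
#' @inheritParams link_mi
#' @return expected absolute projection (same scale as `d`).
#' @export
link_distance <- function(separation_sq) {
  if (any(separation_sq < 0)) stop("separation_sq must be non-negative")
  m <- sqrt(separation_sq) / 2
  2 * stats::dnorm(m) + m * (2 * stats::pnorm(m) - 1)
}

.link_fun <- function(metric) {
  switch(metric,
         mutual_information_bits = link_mi,
         classification_accuracy = link_accuracy,
         hyperplane_distance = link_distance,
         stop("unknown metric: ", metric))
}

.info_timecourse <- function(time_s, value, metric, scope, band_hz = NA_real_) {
  structure(list(time_s = time_s, value = value, metric = metric,
                 scope = scope, band_hz = band_hz),
            class = "info_timecourse")
}

#' @export
print.info_timecourse <- function(x, ...) {
  cat(sprintf("<info_timecourse> %s / %s%s: %d timepoints, range [%.4g, %.4g]\n",
              x$metric, x$scope,
              if (!is.na(x$band_hz)) sprintf(" (%g Hz)", x$band_hz) else "",
              length(x$time_s), min(x$value), max(x$value)))
  invisible(x)
}

#' Narrowband information timecourse
#'
#' Information available when decoding the real (signal-valued) part of one
#' frequency band at each timepoint: `link(c + r cos(2 w t + xi))`. For a
#' nonzero modulation depth the dominant nonzero frequency of this
#' timecourse is exactly twice the band frequency — the frequency-doubling
#' property of instantaneous decoding of oscillatory responses.
#'
#' @param model an [evoked_spectrum_model()].
#' @param band_hz one of the model's frequencies.
#' @param metric `"mutual_information_bits"` (default),
#'   `"classification_accuracy"`, or `"hyperplane_distance"`.
#' @param time_s time grid (defaults to the model's grid).
#' @return an `info_timecourse`.
#' @export
narrowband_info_timecourse <- function(model, band_hz,
                                       metric = "mutual_information_bits",
                                       time_s = model$time_s) {
  sp <- separation_params(model, band_hz)
  .info_timecourse(time_s, .link_fun(metric)(eval_separation(sp, time_s)),
                   metric, "narrowband", band_hz)
}

#' Broadband information timecourse
#'
#' Information available to instantaneous decoding of the full multichannel
#' signal: `link` applied to the broadband separation expansion. Its
#' spectrum is supported on pairwise sum/difference harmonics of the evoked
#' component frequencies and is bounded by twice the highest component
#' frequency (2 Omega), with equality when the top band has nonzero
#' amplitude.
#'
#' @inheritParams narrowband_info_timecourse
#' @return an `info_timecourse`.
#' @export
broadband_info_timecourse <- function(model,
                                      metric = "mutual_information_bits",
                                      time_s = model$time_s) {
  sp <- broadband_separation(model)
  .info_timecourse(time_s, .link_fun(metric)(eval_separation(sp, time_s)),
                   metric, "broadband")
}

#' Complex-spectrum information timecourse
#'
#' Information available when both the real and imaginary STFT coefficients
#' of a band are used as features. The complex feature vector has
#' class-mean difference `2 A exp(i(w t + phi))` and circularly symmetric
#' noise, so the squared separation is `2c` — constant in time — and the
#' timecourse equals `link(2c)` everywhere. It is always greater than or
#' equal to the narrowband timecourse's maximum `link(c + r)` (with
#' equality when `r = c`), and immune to representational aliasing.
#'
#' @inheritParams narrowband_info_timecourse
#' @return an `info_timecourse` (constant over time).
#' @export
complex_info_timecourse <- function(model, band_hz,
                                    metric = "mutual_information_bits",
                                    time_s = model$time_s) {
  sp <- separation_params(model, band_hz)
  val <- .link_fun(metric)(2 * sp$c)
  .info_timecourse(time_s, rep(val, length(time_s)), metric,
                   "complex", band_hz)
}

# ---- Monte-Carlo oracle ----------------------------------------------------

.scope_gaussians <- function(model, t, scope, band_hz) {
  if (scope == "narrowband") {
    b <- .band_index(model, band_hz)
    w <- 2 * pi * model$freqs_hz[b]
    mu <- model$amplitudes[b, ] * cos(w * t + model$phases[b, ])
    list(mu = mu, cov_pos = model$noise_cov[[b]], cov_neg = model$noise_cov[[b]],
         band = b)
  } else if (scope == "complex") {
    b <- .band_index(model, band_hz)
    w <- 2 * pi * model$freqs_hz[b]
    mu <- c(model$amplitudes[b, ] * cos(w * t + model$phases[b, ]),
            model$amplitudes[b, ] * sin(w * t + model$phases[b, ]))
    S2 <- as.matrix(Matrix_bdiag(model$noise_cov[[b]], model$noise_cov[[b]]))
    list(mu = mu, cov_pos = S2, cov_neg = S2, band = b)
  } else if (scope == "broadband") {
    mu <- rep(0, model$n_channels)
    for (b in seq_along(model$freqs_hz)) {
      w <- 2 * pi * model$freqs_hz[b]
      mu <- mu + model$amplitudes[b, ] * cos(w * t + model$phases[b, ])
    }
    Sig <- Reduce(`+`, model$noise_cov)
    list(mu = mu, cov_pos = Sig, cov_neg = Sig, band = NA)
  } else stop("unknown scope: ", scope)
}

Matrix_bdiag <- function(a, b) {
  out <- matrix(0, nrow(a) + nrow(b), ncol(a) + ncol(b))
  out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  out[nrow(a) + seq_len(nrow(b)), ncol(a) + seq_len(ncol(b))] <- b
  out
}

.mvn_logdens <- function(X, mu, chol_cov) {
  # X: n x p; chol_cov upper triangular
  Z <- backsolve(chol_cov, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(Z^2) - sum(log(diag(chol_cov))) -
    0.5 * length(mu) * log(2 * pi)
}

.plugin_mi <- function(mu_diff_half, cov_pos, cov_neg, n_samples) {
  # classes: N(+mu, cov_pos) and N(-mu, cov_neg), equal priors; plug-in MI
  p <- length(mu_diff_half)
  n_pos <- n_samples %/% 2
  n_neg <- n_samples - n_pos
  Rp <- chol(cov_pos); Rn <- chol(cov_neg)
  Xp <- matrix(stats::rnorm(n_pos * p), n_pos, p) %*% Rp
  Xp <- sweep(Xp, 2, mu_diff_half, "+")
  Xn <- matrix(stats::rnorm(n_neg * p), n_neg, p) %*% Rn
  Xn <- sweep(Xn, 2, -mu_diff_half, "+")
  X <- rbind(Xp, Xn)
  own <- c(.mvn_logdens(Xp, mu_diff_half, Rp), .mvn_logdens(Xn, -mu_diff_half, Rn))
  lp <- .mvn_logdens(X, mu_diff_half, Rp)
  ln <- .mvn_logdens(X, -mu_diff_half, Rn)
  m <- pmax(lp, ln)
  mix <- m + log(0.5 * exp(lp - m) + 0.5 * exp(ln - m))
  vals <- (own - mix) / log(2)
  list(estimate = mean(vals), se = stats::sd(vals) / sqrt(length(vals)))
}

#' Monte-Carlo mutual-information estimate at one timepoint
#'
#' Plug-in estimator using the known class-conditional Gaussian densities:
#' samples are drawn from the model's class conditionals at time `t` for
#' the requested scope and the log density ratio is averaged. Serves as the
#' numerical oracle for the analytic timecourses.
#'
#' @param model an [evoked_spectrum_model()].
#' @param t timepoint in seconds.
#' @param scope `"narrowband"`, `"broadband"`, or `"complex"`.
#' @param band_hz band frequency (required for narrowband/complex scopes).
#' @param n_samples number of Monte-Carlo samples (at least 1e4).
#' @param seed integer seed.
#' @return a list with `estimate` (bits) and `se` (standard error).
#' @export
mc_mi_estimate <- function(model, t, scope, band_hz = NULL,
                           n_samples = 1e5, seed = 1) {
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  g <- .scope_gaussians(model, t, scope, band_hz)
  set.seed(seed)
  .plugin_mi(g$mu, g$cov_pos, g$cov_neg, as.integer(n_samples))
}

#' Monte-Carlo information probe for induced (condition-dependent power) effects
#'
#' Same plug-in estimator as [mc_mi_estimate()], but with the model's
#' `induced` scalings applied: the class conditionals keep their evoked
#' means while the residual covariance is scaled per condition
#' (`s^2 Sigma`). With an induced-only contrast (zero evoked amplitudes)
#' the class conditionals are time-invariant, so the estimated information
#' is constant over time up to sampling error; with both effect types
#' present the information never exceeds the sum of the two effects
#' assessed independently (checked empirically).
#'
#' @inheritParams mc_mi_estimate
#' @return a list with `estimate` (bits) and `se`.
#' @export
induced_info_probe <- function(model, t, scope, band_hz = NULL,
                               n_samples = 1e5, seed = 1) {
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  if (is.null(model$induced)) stop("model has no induced scalings")
  g <- .scope_gaussians(model, t, scope, band_hz)
  if (scope %in% c("narrowband", "complex")) {
    s <- model$induced[g$band, ]
    cov_pos <- g$cov_pos * s[1]^2
    cov_neg <- g$cov_neg * s[2]^2
  } else {
    cov_pos <- Reduce(`+`, lapply(seq_along(model$freqs_hz), function(b)
      model$noise_cov[[b]] * model$induced[b, 1]^2))
    cov_neg <- Reduce(`+`, lapply(seq_along(model$freqs_hz), function(b)
      model$noise_cov[[b]] * model$induced[b, 2]^2))
  }
  set.seed(seed)
  .plugin_mi(g$mu, cov_pos, cov_neg, as.integer(n_samples))
}
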