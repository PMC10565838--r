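---
title: "Frequency content and the dynamics of decodable information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency content and the dynamics of decodable information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdyn)
```

## The generative model

`repdyn` studies time-resolved decoding of epoched electrophysiological
data (MEG/EEG-like: multichannel, 100 samples/s, 0.5 s epochs) through a
two-condition generative model. Trial $n$ with label
$y_n \in \{+1, -1\}$ (equal priors, exactly balanced designs) is

$$x_{n,t} \;=\; \mu_t \;+\; \sum_{\omega} \mathrm{Re}\, w_{n,t,\omega},
\qquad
w_{n,t,\omega} \;=\; y_n A_\omega e^{i(\omega t + \phi_\omega)}
  \;+\; \varepsilon_{n,\omega} e^{i\omega t},$$

where $A_\omega$ holds non-negative per-channel amplitudes, $\phi_\omega$
per-channel phases, and $\varepsilon_{n,\omega}$ has independent Gaussian
real and imaginary parts with band covariance $\Sigma_\omega$ (required
symmetric positive definite at construction; there is no pseudo-inverse
fallback for degenerate covariances). The residual coefficient is drawn
once per trial per band and rotated around the epoch, so band noise is
stationary with fixed within-trial amplitude and stimulus-random phase.
The class-conditional distribution of the broadband signal at time $t$ is
Gaussian with mean $\mu_t + y \sum_\omega A_\omega \cos(\omega t +
\phi_\omega)$ and covariance $\sum_\omega \Sigma_\omega$.

Conventions: $t = 0$ at stimulus onset, seconds; frequencies in Hz at
every interface, converted to radians inside formulas; $\mu_t = 0$ by
default (it cancels from every information quantity). A condition that
evokes a response versus a null condition is parameterised by putting the
condition-mean average into $\mu_t$ and the half-difference into
$A_\omega$, as `model_example1()` does.

"Induced" (non-phase-locked) condition effects are modelled by scaling the
residual's Cholesky factor per condition (`induced` in
`evoked_spectrum_model()`), i.e. condition-dependent band power with
uniform phase. The model text this package implements does not fix a
parameterisation for induced effects; a multiplicative amplitude scaling
is the simplest one consistent with "same spatial structure, more power".

## From separation to information

All information metrics here are monotone functions of one scalar: the
squared Mahalanobis separation of the two class means,
$d^2(t) = m(t)' \Sigma^{-1} m(t)$ with $m(t)$ the class-mean difference.
`separation_params()` expands the narrowband separation exactly via the
product-to-sum identity:

$$d^2_\omega(t) = c_\omega + r_\omega \cos(2\omega t + \xi_\omega),
\qquad c_\omega = 2\,\mathrm{Re}(u^H \Sigma_\omega^{-1} u),\quad
r_\omega e^{i\xi_\omega} = 2\, u^T \Sigma_\omega^{-1} u,$$

with $u_j = a_j e^{i\phi_j}$. Two structural facts follow immediately and
are enforced as tested invariants: $r_\omega \le c_\omega$ (separations
are non-negative), and the separation of a component at $\omega$ — hence
any monotone information metric of it — oscillates at exactly $2\omega$.
`broadband_separation()` does the same expansion for the summed signal;
cross-band products contribute harmonics at $\omega_a + \omega_b$ and
$|\omega_a - \omega_b|$, so the information spectrum is supported up to
$2\Omega$, twice the highest evoked frequency. These closed forms are
derived here directly from the Gaussian model and are validated two ways:
against brute-force evaluation of $d^2(t)$ (agreement to $10^{-10}$), and
against a Monte-Carlo plug-in estimator of the mutual information from
the known class conditionals (`mc_mi_estimate()`, 3-SE agreement across
seeded random models).

Three link functions convert separation to a metric (`link_mi()`,
`link_accuracy()`, `link_distance()`):

* mutual information in bits (ceiling 1 for binary equiprobable labels),
  computed by adaptive quadrature along the discriminant projection to
  absolute tolerance $10^{-8}$ — monotone and concave;
* Bayes classification accuracy $\Phi(\sqrt{d^2}/2)$;
* expected absolute standardized discriminant projection (a folded
  normal mean), the "distance from the hyperplane" analogue.

Bits were chosen over nats so that the binary ceiling is exactly 1; no
prior-entropy normalisation is applied (it would not affect any monotone
structure result).

For the complex feature pair $(\mathrm{Re}\,w, \mathrm{Im}\,w)$ the noise
is circularly symmetric and the separation is $2 c_\omega$, constant in
time: complex-spectrum information is flat, at least as large as the
narrowband maximum $\mathrm{link}(c_\omega + r_\omega)$, and free of
representational aliasing. With induced effects no closed form is
attempted; `induced_info_probe()` checks the two structural properties
numerically (time-invariance of induced-only information; subadditivity
of combined effects).

## Representational aliasing

Because information occupies up to $2\Omega$, a decoding-accuracy
timecourse sampled at $F_s$ is alias-free only if $F_s \ge 4\Omega$ —
equivalently, instantaneous-decoding pipelines should low-pass the signal
at one quarter of the sampling rate. `alias_frequency()` folds a
frequency about Nyquist multiples; the boundary convention maps exactly
Nyquist to Nyquist, and $F_s = 4\Omega$ is treated as alias-free (the
doubled component sits exactly at Nyquist and is still resolved).
Empirical dominant frequencies are read off FFT periodograms taken over
an integer number of information cycles, peak = argmax power excluding
DC; `check_sampling()` reports, per band, where the $2\omega$ component
will be observed.

## STFT features

`stft_epochs()` computes sliding-window one-sided DFT coefficients with
bands spaced $1000/\mathrm{window\_ms}$ Hz apart. Choices the underlying
text leaves open, fixed here and documented:

* **Tapers**: periodic (DFT-even) Hamming (default) and Hann, plus
  rectangular. The periodic variants have discrete spectra confined to
  bin offsets $\{0, \pm 1\}$, so a band-centre sinusoid yields an exactly
  unit-magnitude coefficient under the chosen normalisation
  ($2/\sum w$, halved at DC/Nyquist).
* **Demodulation**: coefficients are referenced to the window's centre
  sample, so $\mathrm{Re}\,\hat w(t)$ tracks the instantaneous narrowband
  signal value at $t$ and the coefficient of a stationary oscillation
  rotates at $\omega$ with constant magnitude — the phase-plane geometry
  that motivates complex features. DC and Nyquist bands are exactly real.
* **Hop**: 1 sample by default, so decoding stays per-timepoint;
  configurable for speed.
* **Edges**: symmetric reflection padding by default so the feature time
  axis spans the epoch; a `"valid"` mode restricts to fully interior
  windows (with a whole-epoch window this reproduces the epoch's DFT).
* **Window lengths**: 100 ms for MEG-like data, 50 ms in the fast
  simulation scenarios (band resolution 10 vs 20 Hz).

## Decoding engines

All paradigms share one protocol: stratified k-fold cross-validation
(default 3), fold structure shared across timepoints within a run, and a
linear maximum-margin classifier (`e1071::svm`, linear kernel) with fixed
cost 1 and per-training-fold feature standardization — no hyperparameter
tuning anywhere. Chance is 0.5 and reported accuracy is the fold mean.
`decode_instantaneous()` uses the P raw channel values per timepoint,
`decode_narrowband()` the P real STFT coefficients of one band,
`decode_complex()` the 2P stacked real and imaginary coefficients.
`decode_aggregate()` stacks the per-band complex decoders: the inner loop
produces out-of-fold SVM decision values (signed distances, orientation
normalised to class +1 — richer than hard labels), the outer loop trains
a 100-tree random forest on those band features with repeated stratified
2-fold partitions (default 10 repeats) and averages. The outer loop is
stratified over the two class labels.

`accuracy_psd()` gives the mean-removed periodogram of an accuracy
timecourse — this is where frequency doubling and aliasing become visible
empirically. `cluster_permutation_test()` implements the standard
sign-flip cluster-mass test for paired timecourses: per-timepoint paired
t statistics, clusters of contiguous same-sign suprathreshold points
(two-sided cluster-forming threshold at $\alpha = 0.05$ by default),
null distribution of the maximum absolute cluster mass under random unit
sign flips; p-values are bounded below by $1/(\text{permutations}+1)$.
Its family-wise error calibration is itself tested against 500 null
simulations.

## Simulation scenarios

* `scenario_example1()` — one 10 Hz component vs a null condition:
  information at exactly 20 Hz.
* `scenario_example2()` — components at 10 and 15 Hz with a 20% relative
  condition contrast; harmonic set {5, 20, 25, 30} Hz. The 15 Hz
  component defaults to 0.65 of the 10 Hz amplitude: with exactly equal
  amplitudes the two minor local maxima of the squared separation sit at
  ~12% prominence, making the classic "three distinct peaks per
  fundamental period" structure fragile to the counting rule; a weaker
  second component is equally plausible and makes the structure robust.
  Peaks are counted as local maxima with topographic prominence at least
  10% of the global maximum (`find_peaks()`), on one 0.2 s period treated
  periodically; spectra use a 1% of peak power support threshold.
* `scenario_aliasing()` — the 20 Hz information timecourse sampled at
  160/30 Hz recovers 20/10 Hz.
* `scenario_chirp()` — a linear chirp (default 5 to 50 Hz across the
  0.5 s epoch; channel 2 gated by a 30 ms smoothed step at 0.2 s; 50 ms
  raised-cosine edge ramps to avoid wrap-around splatter in spectra).
  The sweep is taken up to the stated 50 Hz signal-content cap so the
  information support edge lands at twice that, ~100 Hz; the default
  half-difference amplitude 0.5 keeps the MI link in its near-linear
  range so the information spectrum reflects separation structure rather
  than saturation harmonics. The complex-spectrum map (50 ms window)
  instead ridges along the true instantaneous frequency. Per-band noise
  variances for the map are derived exactly from the taper
  ($\sigma^2 \, \mathrm{scale}^2 \sum (w_n \cos\theta_n)^2$, and the sine
  analogue), neglecting the near-zero real/imaginary covariance of
  symmetric tapers.
* `scenario_activations()` — two Gaussian-kernel activations (sd 30 ms,
  centres 0.15/0.35 s on different channels): genuinely non-oscillatory
  structure. Both broadband and 50 ms complex-spectrum information show
  two peaks; a 200 ms window fills in the valley between them, quantified
  by a "pronouncedness" statistic (valley depth relative to the weaker
  peak).

## What the generator does and does not emulate

The simulator reproduces the structure the theory needs: epoched
multichannel data at MEG-like rates, phase-locked oscillatory or
transient evoked differences, stationary band-limited Gaussian noise with
arbitrary spatial covariance, balanced binary labels, optional induced
power effects. It does not emulate 1/f broadband noise, non-Gaussian or
heavy-tailed residuals, trial-to-trial latency jitter, nonstationary
noise, sensor artefacts, or multi-class designs. Passing tests therefore
demonstrate internal consistency of theory and estimators under the
model's assumptions — not robustness of the decoders to real-data
violations of them. The real-data findings reported alongside this theory
(peak pairwise accuracies of specific MEG datasets) are out of scope
here and are replaced by property-based simulation checks.

## Numerical choices and problem sizes

Quadrature for the MI link: `stats::integrate` to absolute tolerance
$10^{-10}$ (spec'd bound $10^{-8}$). SPD validation by symmetric
eigendecomposition (minimum eigenvalue must be positive). FFTs are taken
over integer numbers of cycles wherever a line spectrum is asserted.
Simulation sizes in the test suite were chosen so each statistical check
has comfortable power at its stated threshold: 10,000 trials for
mean-convergence, $10^5$–$10^6$ Monte-Carlo samples for 3-SE oracle
agreement, 1,000 trials for the accuracy-tracking surface, 20 seeds for
the paired complex-vs-narrowband comparison, 500 null simulations
(500 permutations each, 12 units × 30 timepoints) for the family-wise
error calibration of the cluster test, and analytic timecourses on 400 Hz
grids. All simulations take explicit integer seeds and are
bit-reproducible.

## Known limitations

Binary, equiprobable conditions only (multi-class designs are served via
mass pairwise decoding); Gaussian class conditionals only — no
density-free MI estimators; no wavelet or multitaper decompositions; no
anti-alias filter design (the package diagnoses aliasing, it does not
resample data); the induced-effects information bound is probed by Monte
Carlo rather than in closed form.
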