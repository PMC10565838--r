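# repdyn

Tools for understanding how the frequency content of stimulus-evoked
neural responses shapes the temporal dynamics of decodable information in
epoched electrophysiological (MEG/EEG-like) data — for researchers who run
time-resolved multivariate decoding and interpret the resulting accuracy
timecourses.

## The problem and the model

Time-resolved decoding trains a classifier on the multichannel signal at
each timepoint after a stimulus and reads the accuracy timecourse as a
picture of the brain's representational dynamics. `repdyn` models trial
*n* (label *y&#8345;* ∈ {+1, −1}) as a Fourier sum with band-limited
Gaussian noise,

> x&#8345;,&#8348; = μ&#8348; + Σ<sub>ω</sub> Re w&#8345;,&#8348;,<sub>ω</sub>,  w&#8345;,&#8348;,<sub>ω</sub> = y&#8345; A<sub>ω</sub> e^{i(ωt+φ<sub>ω</sub>)} + ε&#8345;,<sub>ω</sub> e^{iωt},  ε&#8345;,<sub>ω</sub> ~ N(0, Σ<sub>ω</sub>) + i N(0, Σ<sub>ω</sub>),

under which every decoding metric is a monotone function of the squared
Mahalanobis separation d²(t) between the class means. Expanding d²(t) in
closed form yields the package's three structural results:

1. **Frequency doubling** — a component at ω Hz produces information at
   exactly 2ω: d²<sub>ω</sub>(t) = c<sub>ω</sub> + r<sub>ω</sub> cos(2ωt + ξ<sub>ω</sub>). Successive
   accuracy peaks can be nothing more than the peaks *and troughs* of one
   evoked oscillation.
2. **Representational aliasing** — broadband information occupies up to
   2Ω (Ω = highest evoked frequency), so accuracy timecourses alias
   unless F&#8347; ≥ 4Ω; signal content must stay below a quarter of the
   sampling rate.
3. **Complex-spectrum stability** — decoding on both real and imaginary
   STFT coefficients sees separation 2c<sub>ω</sub>, constant in time and at
   least the narrowband peak: time-stable, alias-free information.

The package provides the generative simulator, exact separation
expansions with Monte-Carlo oracles, the aliasing arithmetic,
STFT feature extraction, cross-validated decoders for the instantaneous /
narrowband / complex / aggregate paradigms, accuracy spectra,
cluster-based permutation statistics, turn-key scenarios, and a CLI
(`inst/cli/repdyn`).

## Worked example

```r
library(repdyn)

m <- model_example1()   # condition 1: phase-locked 10 Hz on 2 channels; condition 2: null
print(check_sampling(m, 30))

tg <- seq(0, 1 - 1/400, by = 1/400)
mi <- broadband_info_timecourse(m, time_s = tg)
cat("dominant information frequency:", dominant_frequency(mi$value, 400), "Hz\n")
cat("peak / trough MI:", round(max(mi$value), 3), "/", round(min(mi$value), 3), "bits\n")
cx <- complex_info_timecourse(m, 10)
cat("complex-spectrum MI (constant):", round(cx$value[1], 3), "bits\n")

ds <- simulate_trials(m, 300, seed = 1)
sf <- stft_epochs(ds, window_ms = 100)
nb <- decode_narrowband(sf, 10, seed = 1)
cc <- decode_complex(sf, 10, seed = 1)
cat("narrowband decoding: mean", round(mean(nb$accuracy), 3), "peak", round(max(nb$accuracy), 3), "\n")
cat("complex decoding:    mean", round(mean(cc$accuracy), 3), "peak", round(max(cc$accuracy), 3), "\n")
psd <- accuracy_psd(decode_instantaneous(ds, seed = 1))
nz <- psd[psd$freq_hz > 0, ]
cat("accuracy-spectrum peak:", nz$freq_hz[which.max(nz$power)], "Hz\n")
```

Output:

```
<alias_report>
 band_hz info_freq_hz sample_rate_hz nyquist_hz observed_freq_hz is_aliased
      10           20             30         15               10       TRUE
WARNING: 1 band(s) produce representational aliasing; sample at >= 40 Hz
dominant information frequency: 20 Hz
peak / trough MI: 0.721 / 0 bits
complex-spectrum MI (constant): 0.721 bits
narrowband decoding: mean 0.794 peak 0.907
complex decoding:    mean 0.898 peak 0.907
accuracy-spectrum peak: 20 Hz
```

Reading it: the only evoked oscillation is at 10 Hz, yet the information
timecourse oscillates at 20 Hz (and would masquerade as 10 Hz if the
accuracy timecourse were sampled at 30 Hz — hence the alias warning, since
30 < 4Ω = 40). The analytic mutual information swings between 0.721 bits
and zero, while the complex-spectrum information holds the peak value
constantly; empirically, complex decoding lifts the mean accuracy to the
narrowband paradigm's peak (0.90), and the accuracy spectrum of
instantaneous decoding peaks at 20 Hz, twice the evoked frequency.

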