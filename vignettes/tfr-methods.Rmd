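---
title: "Transfer function ratios: model, conventions, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer function ratios: model, conventions, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrnose)
```

## The measurement model

A multichannel chemical sensor array held close to a sample sees a common
gas-concentration input $c(t)$. Treating each channel $i$ as a linear
time-invariant (LTI) system with impulse response $h_i(t)$,

$$ y_i(t) = (h_i * c)(t), \qquad Y_i(f) = H_i(f)\,C(f), $$

so the ratio between two channels,

$$ K_{m,n}(f) \;=\; \frac{Y_m(f)}{Y_n(f)} \;=\; \frac{H_m(f)}{H_n(f)}, $$

does not contain $C(f)$ at all. The transfer functions $H_i$ depend on the
channel's receptor coating and on the analyte (sorption and relaxation
dynamics differ per vapor), so $K_{m,n}(f)$ is an analyte fingerprint that
survives completely uncontrolled gas delivery. This is what makes free-hand
measurements — manually dipping a handheld device into a beaker's headspace
— a viable identification protocol.

The LTI assumption holds as long as the sensors respond linearly in
concentration; at very low concentrations the limiting factor is
signal-to-noise, not linearity.

## Feature extraction conventions

The analysis window is 8 s starting 2 s into a measurement (free-hand
recordings are disturbed at their beginning and end). At the 20 Hz device
rate this is 160 samples, giving DFT bins every $1/8\,\mathrm{s} = 0.125$ Hz
up to the 10 Hz Nyquist frequency. Per channel we subtract the mean, apply a
Hanning taper, and take the unnormalized FFT, keeping bins
$k = 1,\dots,80$; the DC bin holds only the baseline offset and is
discarded. Choices worth stating explicitly:

* **FFT normalization** is irrelevant to the ratios (any factor cancels in
  $Y_m/Y_n$), so the raw unnormalized transform is used throughout; only
  the protocol-waveform magnitude sums (below) depend on this convention.
* **Taper**: the endpoints-zero symmetric Hanning window
  $w_n = \tfrac12(1 - \cos\frac{2\pi n}{N-1})$. An untapered variant
  (`window = "none"`) exists for oracle comparisons, where spectral leakage
  from the taper would mix bins.
* **Magnitude features** are $\log_{10}|K|$ (base configurable to $e$;
  monotonically equivalent for every downstream model, base 10 matches
  conventional magnitude plots).
* **Arguments** are principal values in $(-\pi, \pi]$, not unwrapped:
  unwrapping is ill-defined for noisy ratios sampled every 0.125 Hz.
* **Ordering** is frozen for reproducibility: channel pairs $(m<n)$ in
  lexicographic order; within a pair all log-magnitudes in ascending
  frequency, then all arguments. For 4 channels:
  $6 \times 2 \times 80 = 960$ features.
* **Degenerate bins** ($|Y_n(f)| = 0$) are flagged and poison feature
  assembly with an explicit error, never silently dropped or regularized.
  An optional magnitude floor exists but defaults to off — exact zeros only
  arise in contrived inputs, and silent regularization would bias tests.

### Frequency bands

Band restriction keeps the columns whose bin frequency lies in
$[f_{lo}, f_{hi}]$, inclusive on both ends. The four canonical
quarter-spectrum bands 0.125–2.5, 2.625–5.0, 5.125–7.5, and 7.625–10.0 Hz
each cover 20 of the 80 bins (the edges are themselves bins and are
included), hence 240 columns each, partitioning all 960 features.

## Cluster quality

Analyte separability of a labeled feature dataset is quantified by the
Davies–Bouldin index with its most common instantiation: centroids are
arithmetic means, dispersions $\sigma_i$ are mean Euclidean distances to the
centroid, and

$$ \mathrm{DB} = \frac{1}{n}\sum_i \max_{j \ne i}
   \frac{\sigma_i + \sigma_j}{d(c_i, c_j)}. $$

Smaller is better. The index is invariant under rigid rotation and uniform
scaling of the feature space, which the test suite asserts. PCA score plots
use two components by default; components are made deterministic by forcing
each component's largest-magnitude loading positive. Neither PCA nor the DB
computation standardizes features by default — the cluster analysis operates
on raw TFR features, and standardization is available behind a flag.
Clusters are always defined by the supplied labels; no unsupervised
clustering is performed.

## Classification

Two families, mirroring two philosophies for 960-dimensional features:

* **Logistic regression**: standardize → PCA → ridge-penalized multinomial
  logistic regression. Hyperparameters: `n_components` ∈ {5, 10, 20, 40}
  and inverse regularization `C` ∈ {0.01, 0.1, 1, 10, 100} (ridge penalty
  $1/C$; fit by deterministic coordinate descent).
* **Random forest** on the raw features, no dimensionality reduction.
  Hyperparameter: `n_estimators` ∈ {100, 300, 1000} trees.

The grids span the usual regimes at modest cost and are fully configurable.
Evaluation is 5×5 nested cross-validation: stratified outer folds (the
balanced 30-per-class design makes stratification the natural reading of a
random split, and it stabilizes small-fold estimates); an inner 5-fold grid
search selects hyperparameters by mean validation accuracy with ties going
to the first candidate in grid order; the winner is refit on the full outer
training portion and scored once on the held-out fold. Every fitted
statistic — standardization means and variances, PCA loadings — is estimated
on training portions only, and the report retains those per-fold statistics
so leakage can be asserted by recomputation. Standardization and PCA are
refit inside every fold rather than once globally; the global alternative
would leak test-fold information into the projection. Random forests are
seeded per outer fold from the master seed; identical seed, data, and spec
give a bit-identical report.

## Protocol waveforms

A free-hand protocol with $k$ headspace entries in a measurement is
idealized as a binary concentration waveform: $2k+1$ equal alternating
segments (outside/inside/outside…) across the 8-s window, starting and
ending outside. Segment boundaries fall between samples for $k \in
\{1,3,5\}$ (segments of $8/3$, $8/7$, $8/11$ s); sample $n$ (0-based) takes
the value of the segment its index falls into, i.e. value 1 iff
$\lfloor n(2k+1)/160 \rfloor$ is odd. Spectra of these waveforms are raw
unnormalized DFTs — no taper, no mean subtraction (the mean only affects the
DC bin, which is not reported): the tapered pipeline above is for measured
sensor signals, not for characterizing the input's spectral support. The
0.125–1 Hz magnitude sum (8 bins) then quantifies how much input energy a
protocol places in the band that carries sensing dynamics; it rises from
98.54 (protocol-1) through 103.27 (protocol-3) to 116.96 (protocol-5),
which is the quantitative reason more exposures give better identification.

## The synthetic sensor model

No public recordings of free-hand campaigns exist, so the package ships a
simulator that is itself first-class, tested code. Channel dynamics follow
the two-time-constant viscoelastic picture of nanomechanical sensor
response: gas diffusion into the receptor film ($\tau_s$) and relaxation of
the film modulus ($\tau_r$), both in the 1–100 s range. The kernel family is
the simplest LTI form with exactly that structure,

$$ h(t) = g\left(\frac{a}{\tau_s}e^{-t/\tau_s} +
   \frac{b}{\tau_r}e^{-t/\tau_r}\right), \quad a + b = 1, $$

with closed-form transform
$H(f) = g\,[a/(1 + i2\pi f\tau_s) + b/(1 + i2\pi f\tau_r)]$ — which gives an
exact analytic oracle $H_m/H_n$ for every estimated TFR. Defaults, chosen
once as the simulated study conditions: $\tau$ log-uniform in $[1, 100]$ s,
weights uniform, gains log-uniform in $[0.5, 2]$; models are redrawn until
every analyte pair differs by at least 0.3 RMS across the sub-1-Hz TFR
feature curves, guaranteeing distinct signatures. Output noise is additive
white Gaussian, $\sigma = 0.003$ against O(1) gains — a few percent of a
typical response peak, consistent with the visually clean traces a handheld
device produces at headspace concentrations. Because signal power falls off
with frequency while the noise floor is flat, high-frequency TFR bins are
noise-dominated exactly as in real arrays.

Free-hand variability is layered on the ideal binary waveform: boundary
jitter (±10% of a segment), a log-uniform ×[0.5, 2] amplitude scale per
measurement, and 0.2-s first-order mixing smoothing. All three are
invisible to exact TFRs by linearity and input independence, so they add
realism without corrupting labels. Measurements are simulated over 10 s
with the protocol spanning the central 8 s and the analysis window at
2–10 s, mimicking the disturbed lead-in of real hand motion.

### Two convolution modes, and why both exist

* **Transient** (the realistic mode): causal trapezoid-rule convolution of
  the sampled impulse response with the input, from rest. Verified against
  the closed-form step response to $10^{-3}$.
* **Steady-periodic** (the validation mode): the input is treated as one
  period of a periodic signal and each DFT bin is multiplied by the exact
  $H(f)$ at that bin. By the circular-convolution theorem the output
  spectrum is exactly $H(f)C(f)$, so untapered TFR estimates equal the
  analytic oracle to machine precision wherever the input has energy. This
  turns the method's central input-independence claim into a machine-checked
  identity rather than an approximation.

One caveat is inherent to sampling: the DFT of a real signal is necessarily
real at the Nyquist bin, so the complex phase of $H$ at 10 Hz is
unidentifiable from any real recording. Oracle comparisons therefore cover
all adequately excited bins below Nyquist (input energy above $10^{-6}$ of
total); there the estimates match the closed form to better than
$10^{-10}$ relative.

## What the synthetic benchmark does and does not show

The default benchmark (4 analytes × 30 measurements, protocol-5, default
noise, fixed seed) reproduces the qualitative structure of a real free-hand
campaign: random-forest nested-CV accuracy ≥ 0.95, and both cluster quality
and accuracy degrade from the 0.125–2.5 Hz band to the 7.625–10 Hz band.
These are properties of the simulator's construction — dynamics below 1 Hz,
flat noise — so passing them validates the pipeline's correctness and the
method's internal logic, not its performance on real vapors. Real
measurement campaigns add effects the generator deliberately omits:
receptor aging and drift, temperature and humidity sensitivity,
concentration nonlinearity, plume turbulence, and inter-device variability.
Published results on real 4-analyte campaigns (DB indices near 4–5,
accuracies 0.96–0.98) are context, not targets; they are not reproducible
without the original recordings.

## Problem sizes and numerical choices

The shipped tests run the full benchmark at its native size (120 recordings
of 200 samples; nested CV with the default grids) plus property checks on
160-sample windows; the whole suite completes in well under a minute on a
single core. Other conventions: window length × rate must be integral (the
8-s/160-sample window is the default; the occasionally quoted 7-s variant
of the analysis region is not used because all frequency arithmetic
requires 160 samples); recording time columns are validated against the
declared rate to 1 µs and then discarded (the device clock is
authoritative); delimiters are auto-detected between comma and tab; feature
export uses 17 significant digits for bit-exact re-import; ties in grid
search and the sign of PCA components are fixed deterministically as
described above.
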