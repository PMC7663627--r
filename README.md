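# tfrnose

Gas-flow-independent odor identification from multichannel chemical sensor
arrays, based on **transfer function ratios (TFRs)**.

## The problem

Conventional electronic noses need pumps and mass-flow controllers because
the features they extract depend on how the sample gas reaches the sensors.
That rules out the simplest possible measurement: waving a small handheld
sensor array over a sample ("free-hand measurement").

Model each channel *i* of a compact sensor array as a linear time-invariant
system driven by the common gas concentration *c(t)*:

    y_i(t) = (h_i * c)(t)        ⇒        Y_i(f) = H_i(f) · C(f)

Because all channels sit millimetres apart, *C(f)* is shared, and the ratio
of two channels' output spectra

    K_m,n(f) = Y_m(f) / Y_n(f) = H_m(f) / H_n(f)

cancels the input entirely. `K_m,n(f)` depends only on the sensor coatings
and the analyte — it is a gas-flow-independent fingerprint that can be
computed from the sensing signals alone. `tfrnose` implements the complete
workflow around this statistic:

* **Feature extraction** — windowed recordings → mean subtraction, Hanning
  taper, FFT → pairwise complex ratios → concatenated `log10|K|` and
  `arg K` features (for a 4-channel, 160-sample, 20-Hz window: 6 pairs × 2
  kinds × 80 bins = 960 features at 0.125-Hz resolution).
* **Cluster quality** — PCA score projection and the Davies–Bouldin index
  over labeled feature datasets, overall and per frequency band.
* **Classification** — ridge multinomial logistic regression
  (standardize + PCA) and random forests, evaluated by leakage-free 5×5
  nested cross-validation with grid search.
* **Protocol analysis** — idealized binary concentration waveforms for
  free-hand protocols (the device enters the headspace *k* times), their
  magnitude spectra, and sub-band coverage sums.
* **Simulation** — a ground-truth LTI sensor model (two-time-constant
  viscoelastic kernels, 1–100 s) with a closed-form TFR oracle and a
  generator for labeled synthetic free-hand datasets.

## Worked example

Simulate a measurement campaign (4 analytes × 30 free-hand measurements,
protocol-5), extract TFR features, and evaluate cluster quality and
classification accuracy:

```r
library(tfrnose)

model  <- default_model(seed = 1)            # ground-truth sensor kernels
config <- simulation_config(seed = 1)        # protocol-5, jitter, noise
m  <- generate_dataset(model, config, n_per_analyte = 30, dir = tempfile())
ds <- build_feature_dataset(m)
print(ds)
#> <tfr_dataset> 120 measurements x 960 features; classes: acetone (30),
#>   hexane (30), methanol (30), water (30)

band_db_scan(ds, canonical_bands())
#>       band  f_lo f_hi n_features db_index
#> 1   data_I 0.125  2.5        240 5.678919
#> 2  data_II 2.625  5.0        240 7.496021
#> 3 data_III 5.125  7.5        240 8.519621
#> 4  data_IV 7.625 10.0        240 8.072416

nested_cv(ds, model_spec("random_forest"), seed = 1)
#> <tfr_cv_report> random_forest: accuracy 1.000 +/- 0.000
#>   (folds: 1.00, 1.00, 1.00, 1.00, 1.00)
```

The Davies–Bouldin index (smaller = better-separated analyte clusters) is
lowest in the 0.125–2.5 Hz band and deteriorates at high frequency: the
sensor kernels' 1–100 s time constants put all analyte-specific TFR
structure below ~1 Hz, while high-frequency bins are noise-dominated. The
nested-CV report shows per-fold held-out accuracies for a random forest on
the raw 960-dimensional features.

Protocol coverage of that informative sub-1-Hz band:

```r
for (k in c(1, 3, 5))
  cat(sprintf("Protocol-%d: 0.125-1 Hz magnitude sum %.2f\n", k,
              band_magnitude_sum(make_protocol_waveform(k))))
#> Protocol-1: 0.125-1 Hz magnitude sum 98.54
#> Protocol-3: 0.125-1 Hz magnitude sum 103.27
#> Protocol-5: 0.125-1 Hz magnitude sum 116.96
```

More headspace entries per measurement spread the input energy across more
low-frequency bins, which is why protocol-5 supports the best
identification.

A command-line wrapper is installed as `exec/tfrnose` with subcommands
`simulate`, `extract`, `cluster`, `classify`, and `protocol-sim`, all driven
by one YAML config (see `?read_run_config`).

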