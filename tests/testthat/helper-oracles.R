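# Independent oracles and shared fixtures for the test suite.

# Direct O(n^2) DFT sum: the brute-force oracle against which fft-based
# spectra are checked. Unnormalized forward transform, bin k (0-based).
direct_dft <- function(x, k) {
  n <- length(x)
  idx <- 0:(n - 1)
  sum(x * exp(-2i * pi * k * idx / n))
}

direct_dft_all <- function(x) {
  vapply(0:(length(x) - 1), function(k) direct_dft(x, k),
         complex(1))
}

# A reproducible 4-channel test recording.
test_recording <- function(n = 160, n_ch = 4, rate = 20, seed = 42,
                           label = NULL) {
  set.seed(seed)
  recording(matrix(rnorm(n * n_ch), n, n_ch), rate, label = label)
}

# Bins of an input spectrum carrying enough energy for a meaningful TFR
# estimate; the Nyquist bin is always excluded because a real sampled signal
# cannot carry the complex phase of H at Nyquist.
excited_bins <- function(input, rel_energy = 1e-6) {
  n <- length(input)
  C <- stats::fft(input)[2:(n / 2 + 1)]
  ok <- Mod(C)^2 > rel_energy * sum(Mod(C)^2)
  ok[length(ok)] <- FALSE
  ok
}

# Well-separated 4-class dataset for classifier sanity checks: tight
# Gaussian blobs around distant centers.
separable_dataset <- function(n_per_class = 30, p = 8, seed = 7) {
  set.seed(seed)
  classes <- paste0("class", 1:4)
  centers <- diag(4)[, rep(1:4, length.out = p)] * 10
  rows <- do.call(rbind, lapply(1:4, function(ci)
    matrix(rnorm(n_per_class * p, sd = 0.5), n_per_class, p) +
      rep(centers[ci, ], each = n_per_class)))
  feature_dataset(rows, rep(classes, each = n_per_class),
                  data.frame(pair = "1,2",
                             kind = rep(c("log_magnitude", "argument"),
                                        length.out = p),
                             frequency = seq_len(p) * 0.125))
}

# The default synthetic 4-analyte free-hand benchmark (protocol-5,
# 30 measurements per analyte, default noise), built once per test run.
.benchmark_cache <- new.env(parent = emptyenv())
benchmark_dataset <- function() {
  if (is.null(.benchmark_cache$ds)) {
    model <- default_model(seed = 1)
    config <- simulation_config(seed = 1)
    dir <- file.path(tempdir(), "tfrnose-benchmark")
    m <- generate_dataset(model, config, n_per_analyte = 30L, dir = dir)
    .benchmark_cache$model <- model
    .benchmark_cache$ds <- build_feature_dataset(m)
  }
  list(ds = .benchmark_cache$ds, model = .benchmark_cache$model)
}
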