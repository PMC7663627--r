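test_that("default models are complete, reproducible, and in range", {
  m <- default_model(seed = 4)
  expect_equal(dim(m$kernels), c(4, 4))
  expect_equal(sum(lengths(m$kernels) > 0), 16)
  taus <- unlist(lapply(m$kernels, function(k) c(k$tau_s, k$tau_r)))
  expect_true(all(taus >= 1 & taus <= 100))
  ab <- vapply(m$kernels, function(k) k$a + k$b, numeric(1))
  expect_true(all(abs(ab - 1) < 1e-12))
  m2 <- default_model(seed = 4)
  expect_identical(m, m2)
  m3 <- default_model(seed = 5)
  expect_false(identical(m$kernels[[1, 1]], m3$kernels[[1, 1]]))
})

test_that("analytic TFRs obey closed-form identities", {
  m <- default_model(seed = 4)
  kp <- kernel_params(a = 0.3, tau_s = 2, tau_r = 40, gain = 1.2)
  # identical kernels on both channels: K = 1
  m$kernels[[1, "water"]] <- kp
  m$kernels[[2, "water"]] <- kp
  f <- seq(0.125, 10, by = 0.125)
  expect_lt(max(Mod(analytic_tfr(m, "water", c(1, 2), f) - 1)), 1e-12)
  # same time constants, different gains: K is the real gain ratio
  m$kernels[[2, "water"]] <- kernel_params(a = 0.3, tau_s = 2, tau_r = 40,
                                           gain = 0.4)
  expect_lt(max(Mod(analytic_tfr(m, "water", c(1, 2), f) - 3)), 1e-12)
  # f -> 0: statics dominate, K -> gain ratio for any kernel pair
  m2 <- default_model(seed = 9)
  k0 <- analytic_tfr(m2, "hexane", c(1, 3), 1e-9)
  g <- m2$kernels[[1, "hexane"]]$gain / m2$kernels[[3, "hexane"]]$gain
  expect_equal(Re(k0), g, tolerance = 1e-6)
  expect_lt(abs(Im(k0)), 1e-6)
  expect_error(analytic_tfr(m2, "cola", c(1, 2), 1), "unknown analyte")
})

test_that("transient convolution matches the closed-form step response", {
  m <- default_model(seed = 4, noise_sigma = 0)
  m$kernels[[1, "water"]] <- kernel_params(a = 1, tau_s = 5, tau_r = 3,
                                           gain = 2)
  out <- simulate_response(m, "water", rep(1, 160), mode = "transient")
  t <- (0:159) / 20
  expect_lt(max(abs(out$samples[, 1] - 2 * (1 - exp(-t / 5)))), 1e-3)
  # zero input, zero noise -> zero output
  z <- simulate_response(m, "water", rep(0, 160), mode = "transient")
  expect_true(all(z$samples == 0))
  # linearity: doubling the input doubles every sample exactly
  x <- make_protocol_waveform(3)$values
  y1 <- simulate_response(m, "water", x, mode = "transient")
  y2 <- simulate_response(m, "water", 2 * x, mode = "transient")
  expect_identical(y2$samples, 2 * y1$samples)
  expect_equal(y1$label, "water")
})

test_that("steady-periodic output recovers the analytic TFR at excited bins", {
  m <- default_model(seed = 4)
  for (input in list(make_protocol_waveform(5)$values,
                     make_protocol_waveform(1)$values)) {
    out <- simulate_response(m, "methanol", input, mode = "steady_periodic",
                             noise_sigma = 0)
    sp <- preprocess_and_fft(out, window = "none")
    tfrs <- compute_tfrs(sp)
    ok <- excited_bins(input)
    for (p in seq_len(nrow(tfrs$pairs))) {
      truth <- analytic_tfr(m, "methanol", tfrs$pairs[p, ],
                            sp$frequencies[ok])
      err <- Mod(tfrs$values[ok, p] - truth) / Mod(truth)
      expect_lt(max(err), 1e-9)
    }
  }
})

test_that("TFRs are input-independent and amplitude-invariant", {
  m <- default_model(seed = 4)
  set.seed(21)
  # two different inputs with full spectral support
  in1 <- runif(160)
  in2 <- make_protocol_waveform(5)$values + 0.3 * runif(160)
  k <- lapply(list(in1, in2), function(x) {
    out <- simulate_response(m, "acetone", x, mode = "steady_periodic",
                             noise_sigma = 0)
    compute_tfrs(preprocess_and_fft(out, window = "none"))
  })
  ok <- excited_bins(in1) & excited_bins(in2)
  rel <- Mod(k[[1]]$values[ok, ] - k[[2]]$values[ok, ]) /
    Mod(k[[2]]$values[ok, ])
  expect_lt(max(rel), 1e-6)
  # and they match the oracle
  truth <- analytic_tfr(m, "acetone", c(1, 2), k[[1]]$frequencies[ok])
  expect_lt(max(Mod(k[[1]]$values[ok, 1] - truth) / Mod(truth)), 1e-6)
  # scaling the input leaves every TFR bin unchanged
  out1 <- simulate_response(m, "acetone", in1, mode = "steady_periodic",
                            noise_sigma = 0)
  out2 <- simulate_response(m, "acetone", 17.3 * in1,
                            mode = "steady_periodic", noise_sigma = 0)
  k1 <- compute_tfrs(preprocess_and_fft(out1, window = "none"))
  k2 <- compute_tfrs(preprocess_and_fft(out2, window = "none"))
  expect_lt(max(Mod(k2$values[ok, ] - k1$values[ok, ]) /
                  Mod(k1$values[ok, ])), 1e-6)
})

test_that("generated datasets are reproducible and correctly bookkept", {
  m <- default_model(seed = 4)
  cfg <- simulation_config(seed = 33)
  d1 <- withr::local_tempdir()
  man <- generate_dataset(m, cfg, n_per_analyte = 3, dir = d1)
  expect_equal(nrow(man$entries), 12)
  expect_equal(sort(as.integer(table(man$entries$label))), rep(3L, 4))
  expect_true(all(file.exists(man$entries$path)))
  # identical seeds give bit-identical recordings and manifests
  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(m, cfg, n_per_analyte = 3, dir = d2)
  expect_identical(man$entries$label, man2$entries$label)
  for (i in seq_len(nrow(man$entries)))
    expect_identical(readLines(man$entries$path[i]),
                     readLines(man2$entries$path[i]))
  # no jitter, fixed amplitude, no noise -> identical recordings per analyte
  m0 <- default_model(seed = 4, noise_sigma = 0)
  cfg0 <- simulation_config(jitter = 0, amplitude_range = c(1, 1), seed = 1)
  d3 <- withr::local_tempdir()
  man0 <- generate_dataset(m0, cfg0, n_per_analyte = 2, dir = d3)
  for (an in m0$analytes) {
    paths <- man0$entries$path[man0$entries$label == an]
    expect_identical(readLines(paths[1]), readLines(paths[2]))
  }
})

test_that("sensor models round-trip through YAML", {
  m <- default_model(seed = 4)
  p <- file.path(withr::local_tempdir(), "model.yaml")
  write_sensor_model(m, p)
  back <- read_sensor_model(p)
  expect_equal(back$analytes, m$analytes)
  expect_equal(back$noise_sigma, m$noise_sigma)
  f <- seq(0.125, 10, by = 0.125)
  expect_equal(analytic_tfr(back, "water", c(1, 4), f),
               analytic_tfr(m, "water", c(1, 4), f), tolerance = 1e-12)
})
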