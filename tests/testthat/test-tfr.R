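test_that("a 160-sample, 20-Hz window yields 80 bins from 0.125 to 10 Hz", {
  sp <- preprocess_and_fft(test_recording())
  expect_equal(length(sp$frequencies), 80)
  expect_equal(sp$frequencies, (1:80) * 0.125)
  expect_equal(dim(sp$components), c(80, 4))
  expect_error(preprocess_and_fft(test_recording(n = 159)), "even")
})

test_that("a constant channel transforms to exactly zero at every bin", {
  rec <- recording(cbind(rep(3.7, 160), rnorm(160)), 20)
  sp <- preprocess_and_fft(rec)
  expect_true(all(Mod(sp$components[, 1]) == 0))
})

test_that("tapered spectra match a direct DFT-sum oracle", {
  # cosine at exactly bin 10: leakage from the Hanning taper concentrates in
  # bins 9-11 with bin 10 dominant
  n <- 160
  x <- cos(2 * pi * 10 * (0:(n - 1)) / n)
  rec <- recording(cbind(x, x), 20)
  sp <- preprocess_and_fft(rec)
  taper <- tfrnose:::hanning_window(n)
  oracle <- direct_dft_all((x - mean(x)) * taper)[2:(n / 2 + 1)]
  expect_lt(max(Mod(sp$components[, 1] - oracle)), 1e-9)
  mags <- Mod(sp$components[, 1])
  expect_equal(which.max(mags), 10)
  expect_gt(sum(mags[9:11]), 0.99 * sum(mags))
})

test_that("TFR pairs follow lexicographic order and basic identities", {
  sp <- preprocess_and_fft(test_recording())
  tfrs <- compute_tfrs(sp)
  expect_equal(tfrs$pairs,
               rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)))
  # identical channels give K = 1 everywhere
  x <- rnorm(160)
  same <- compute_tfrs(preprocess_and_fft(recording(cbind(x, x), 20)))
  expect_lt(max(Mod(same$values[, 1] - 1)), 1e-12)
  # scaling one channel scales the ratio magnitude exactly
  rec <- test_recording()
  scaled <- rec
  scaled$samples[, 1] <- scaled$samples[, 1] * 3.5
  k0 <- compute_tfrs(preprocess_and_fft(rec))$values[, 1]
  k1 <- compute_tfrs(preprocess_and_fft(scaled))$values[, 1]
  expect_equal(Mod(k1), 3.5 * Mod(k0), tolerance = 1e-12)
})

test_that("reciprocity and the chain rule hold across channel counts", {
  for (nch in 2:6) {
    set.seed(nch)
    sp <- preprocess_and_fft(recording(matrix(rnorm(160 * nch), 160, nch), 20))
    tfrs <- compute_tfrs(sp)
    expect_equal(nrow(tfrs$pairs), nch * (nch - 1) / 2)
    # reciprocity: K[m,n] * K[n,m] = 1 (K[n,m] recomputed as Y_n / Y_m)
    for (p in seq_len(nrow(tfrs$pairs))) {
      m <- tfrs$pairs[p, 1]; n <- tfrs$pairs[p, 2]
      k_rev <- sp$components[, n] / sp$components[, m]
      expect_lt(max(Mod(tfrs$values[, p] * k_rev - 1)), 1e-12)
    }
    # chain rule on the first channel triple
    if (nch >= 3) {
      k12 <- sp$components[, 1] / sp$components[, 2]
      k23 <- sp$components[, 2] / sp$components[, 3]
      k13 <- sp$components[, 1] / sp$components[, 3]
      expect_lt(max(Mod(k12 * k23 - k13) / Mod(k13)), 1e-12)
    }
    # feature length for arbitrary channel count
    fv <- assemble_features(tfrs)
    expect_equal(length(fv$values), nch * (nch - 1) / 2 * 2 * 80)
  }
})

test_that("feature assembly order, principal arguments, and log base", {
  tfrs <- compute_tfrs(preprocess_and_fft(test_recording()))
  fv <- assemble_features(tfrs)
  expect_equal(length(fv$values), 960)
  expect_equal(nrow(fv$descriptors), 960)
  # block layout: pair (1,2) log-magnitudes first, then its arguments
  expect_equal(fv$descriptors$pair[1:160], rep("1,2", 160))
  expect_equal(fv$descriptors$kind[1:80], rep("log_magnitude", 80))
  expect_equal(fv$descriptors$kind[81:160], rep("argument", 80))
  expect_equal(fv$descriptors$frequency[1:80], (1:80) * 0.125)
  args <- fv$values[fv$descriptors$kind == "argument"]
  expect_true(all(args > -pi & args <= pi))
  # identical channels give the all-zero vector
  x <- rnorm(160)
  rec0 <- recording(cbind(x, x), 20)
  fv0 <- assemble_features(compute_tfrs(preprocess_and_fft(rec0)))
  expect_lt(max(abs(fv0$values)), 1e-12)
  # natural log differs from base 10 by log(10) on magnitude entries
  fve <- assemble_features(tfrs, log_base = exp(1))
  lm <- fv$descriptors$kind == "log_magnitude"
  expect_equal(fve$values[lm], fv$values[lm] * log(10), tolerance = 1e-12)
  expect_equal(fve$values[!lm], fv$values[!lm])
})

test_that("swapping a pair's channels negates its log-magnitude and argument", {
  rec <- test_recording(n_ch = 2)
  swapped <- recording(rec$samples[, c(2, 1)], 20)
  f1 <- assemble_features(compute_tfrs(preprocess_and_fft(rec)))
  f2 <- assemble_features(compute_tfrs(preprocess_and_fft(swapped)))
  lm <- f1$descriptors$kind == "log_magnitude"
  expect_equal(f2$values[lm], -f1$values[lm], tolerance = 1e-10)
  # arguments negate modulo the 2*pi wrap at the +/- pi boundary
  d <- (f2$values[!lm] + f1$values[!lm]) %% (2 * pi)
  expect_true(all(pmin(d, 2 * pi - d) < 1e-10))
})

test_that("degenerate denominator bins are flagged, never dropped", {
  sp <- preprocess_and_fft(test_recording(n_ch = 2))
  sp$components[5, 2] <- 0 + 0i
  tfrs <- compute_tfrs(sp)
  expect_true(tfrs$degenerate[5, 1])
  expect_true(is.na(tfrs$values[5, 1]))
  expect_equal(sum(tfrs$degenerate), 1)
  expect_error(assemble_features(tfrs), "pair \\(1,2\\) at 0.625 Hz")
  # a magnitude floor widens the degenerate set
  sp$components[6, 2] <- 1e-15 + 0i
  expect_equal(sum(compute_tfrs(sp, floor = 1e-12)$degenerate), 2)
})

test_that("band selection keeps inclusive edges and rejects empty bands", {
  fv <- assemble_features(compute_tfrs(preprocess_and_fft(test_recording())))
  ds <- feature_dataset(matrix(fv$values, 1), "water", fv$descriptors)
  counts <- vapply(canonical_bands(), function(b)
    ncol(select_band(ds, b)$matrix), numeric(1))
  # each canonical band spans 20 of the 80 bins (inclusive edges), and both
  # feature kinds are kept for all 6 pairs: 20 * 2 * 6 = 240
  expect_equal(unname(counts), c(240, 240, 240, 240))
  expect_equal(sum(counts), 960)
  # full-range band is the identity
  expect_equal(ncol(select_band(ds, band(0.125, 10))$matrix), 960)
  expect_error(select_band(ds, band(10.5, 11)), "no features")
  expect_error(band(3, 2), "f_lo")
})

test_that("dataset assembly follows the manifest and reports failing files", {
  dir <- withr::local_tempdir()
  set.seed(9)
  labels <- rep(c("water", "hexane"), each = 3)
  paths <- file.path(dir, sprintf("r%d.csv", 1:6))
  for (i in 1:6)
    write_recording(recording(matrix(rnorm(200 * 4), 200, 4), 20), paths[i])
  m <- manifest(data.frame(path = paths, label = labels), 20, 2, 8)
  ds <- build_feature_dataset(m)
  expect_equal(dim(ds$matrix), c(6, 960))
  expect_equal(ds$labels, labels)
  # single-recording manifest
  m1 <- manifest(data.frame(path = paths[1], label = "water"), 20, 2, 8)
  expect_equal(dim(build_feature_dataset(m1)$matrix), c(1, 960))
  # an unreadable entry is reported with its path
  m_bad <- manifest(data.frame(path = c(paths[1], file.path(dir, "gone.csv")),
                               label = c("water", "hexane")), 20, 2, 8)
  expect_error(build_feature_dataset(m_bad), "gone.csv")
})

test_that("feature datasets export and re-import bit-exactly", {
  dir <- withr::local_tempdir()
  fv <- assemble_features(compute_tfrs(preprocess_and_fft(test_recording())))
  ds <- feature_dataset(rbind(fv$values, fv$values * 1.5),
                        c("water", "hexane"), fv$descriptors)
  stem <- file.path(dir, "features")
  write_feature_dataset(ds, stem)
  back <- read_feature_dataset(stem)
  expect_identical(back$matrix[1, ], ds$matrix[1, ])
  expect_identical(back$matrix[2, ], ds$matrix[2, ])
  expect_identical(back$labels, ds$labels)
  expect_equal(back$descriptors$frequency, ds$descriptors$frequency)
})
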