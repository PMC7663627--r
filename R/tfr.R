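#' Hanning taper
#'
#' Symmetric endpoints-zero Hanning window,
#' `w[n] = 0.5 * (1 - cos(2*pi*n/(N-1)))` for `n = 0..N-1`.
#'
#' @param n Window length.
#' @return Numeric vector of length `n`.
#' @keywords internal
hanning_window <- function(n) {
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' Channel spectra of a windowed recording
#'
#' Per channel: subtract the channel mean, apply the taper, and take the
#' unnormalized discrete Fourier transform. Only the positive-frequency bins
#' `k = 1 .. N/2` are retained (frequencies `k * rate / N` up to Nyquist); the
#' DC bin carries only the offset and is discarded. For the standard
#' 160-sample window at 20 Hz this gives 80 bins at 0.125, 0.250, ..., 10 Hz.
#'
#' The transform is unnormalized (no `1/N`); any normalization cancels in the
#' transfer function ratios downstream.
#'
#' @param rec A [recording()]; the sample count must be even.
#' @param window Taper: `"hanning"` (default, as used for measured signals) or
#'   `"none"` (raw DFT; used when comparing against the simulator's
#'   closed-form oracle, where leakage from a taper would mix bins).
#' @return An object of class `tfr_spectrum`: list with `components` (complex
#'   `n_bins x n_channels` matrix), `frequencies` (Hz), `window_kind`,
#'   `channel_names`, `label`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(640), 160, 4), sampling_rate = 20)
#' sp <- preprocess_and_fft(rec)
#' range(sp$frequencies)  # 0.125 .. 10 Hz
preprocess_and_fft <- function(rec, window = c("hanning", "none")) {
  stopifnot(inherits(rec, "tfr_recording"))
  window <- match.arg(window)
  n <- n_samples(rec)
  if (n %% 2L != 0L)
    stop("spectral analysis requires an even number of samples, got ", n)
  if (!all(is.finite(rec$samples)))
    stop("recording contains non-finite samples")
  taper <- if (window == "hanning") hanning_window(n) else rep(1, n)
  keep <- 2:(n / 2 + 1)  # DFT bins k = 1 .. N/2
  comp <- apply(rec$samples, 2L, function(x) {
    stats::fft((x - mean(x)) * taper)[keep]
  })
  freqs <- (seq_len(n / 2)) * rec$sampling_rate / n
  structure(
    list(components = comp, frequencies = freqs, window_kind = window,
         channel_names = rec$channel_names, label = rec$label),
    class = "tfr_spectrum")
}

#' Channel pairs in lexicographic order
#' @param n_channels Number of channels.
#' @return Two-column integer matrix of pairs `(m, n)` with `m < n`.
#' @keywords internal
channel_pairs <- function(n_channels) {
  t(utils::combn(n_channels, 2L))
}

#' Transfer function ratios between channel pairs
#'
#' For every channel pair `(m, n)` with `m < n` (lexicographic order), the
#' transfer function ratio `K[m,n](f) = Y[m](f) / Y[n](f)` is computed per
#' frequency bin. Because the gas-concentration input is common to all
#' channels, this ratio equals the ratio of the channels' transfer functions
#' and does not depend on the input — the property that makes free-hand
#' measurements possible.
#'
#' Bins where the denominator magnitude is zero (or below `floor`, if set) are
#' flagged degenerate and set to `NA`; they are never silently dropped.
#'
#' @param spec A `tfr_spectrum` from [preprocess_and_fft()].
#' @param floor Optional magnitude floor for the denominator; default `0`
#'   (off), i.e. only exact zeros are degenerate.
#' @return An object of class `tfr_set`: list with `pairs` (matrix),
#'   `values` (complex `n_bins x n_pairs`), `degenerate` (logical matrix),
#'   `frequencies`, `channel_names`, `label`.
#' @export
compute_tfrs <- function(spec, floor = 0) {
  stopifnot(inherits(spec, "tfr_spectrum"))
  nc <- ncol(spec$components)
  if (nc < 2L) stop("at least 2 channels are required")
  pairs <- channel_pairs(nc)
  np <- nrow(pairs)
  nb <- nrow(spec$components)
  values <- matrix(complex(real = NA_real_, imaginary = NA_real_), nb, np)
  degen <- matrix(FALSE, nb, np)
  for (p in seq_len(np)) {
    num <- spec$components[, pairs[p, 1L]]
    den <- spec$components[, pairs[p, 2L]]
    bad <- Mod(den) <= floor
    degen[, p] <- bad
    values[!bad, p] <- num[!bad] / den[!bad]
  }
  colnames(values) <- paste0("K", pairs[, 1L], ",", pairs[, 2L])
  structure(
    list(pairs = pairs, values = values, degenerate = degen,
         frequencies = spec$frequencies, channel_names = spec$channel_names,
         label = spec$label),
    class = "tfr_set")
}

#' Assemble the TFR feature vector
#'
#' Splits each complex ratio into log-magnitude and argument and concatenates
#' them: for each pair in lexicographic order, all `log|K|` in ascending
#' frequency, then all `arg(K)` in ascending frequency. Arguments are
#' principal values in `(-pi, pi]`; no phase unwrapping is attempted. For 4
#' channels and 80 bins this yields the standard 960-dimensional vector
#' (6 pairs x 2 kinds x 80 bins).
#'
#' @param tfrs A `tfr_set` from [compute_tfrs()].
#' @param log_base Base for the magnitude logarithm, `10` (default) or
#'   `exp(1)`.
#' @return An object of class `tfr_feature_vector`: list with `values`
#'   (numeric vector) and `descriptors` (data frame with columns `pair`,
#'   `kind`, `frequency`).
#' @export
assemble_features <- function(tfrs, log_base = 10) {
  stopifnot(inherits(tfrs, "tfr_set"))
  if (!log_base %in% c(10, exp(1)))
    stop("log_base must be 10 or exp(1)")
  if (any(tfrs$degenerate)) {
    idx <- which(tfrs$degenerate, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "degenerate TFR bin: pair (%d,%d) at %g Hz has zero denominator spectrum",
      tfrs$pairs[idx[2L], 1L], tfrs$pairs[idx[2L], 2L],
      tfrs$frequencies[idx[1L]]))
  }
  np <- nrow(tfrs$pairs)
  nb <- length(tfrs$frequencies)
  values <- numeric(0)
  pair_lab <- character(0)
  kind <- character(0)
  freq <- numeric(0)
  for (p in seq_len(np)) {
    k <- tfrs$values[, p]
    arg <- Arg(k)
    arg[arg <= -pi] <- pi  # principal value in (-pi, pi]
    lab <- sprintf("%d,%d", tfrs$pairs[p, 1L], tfrs$pairs[p, 2L])
    values <- c(values, log(Mod(k), base = log_base), arg)
    pair_lab <- c(pair_lab, rep(lab, 2L * nb))
    kind <- c(kind, rep(c("log_magnitude", "argument"), each = nb))
    freq <- c(freq, tfrs$frequencies, tfrs$frequencies)
  }
  structure(
    list(values = values,
         descriptors = data.frame(pair = pair_lab, kind = kind,
                                  frequency = freq,
                                  stringsAsFactors = FALSE)),
    class = "tfr_feature_vector")
}

#' Feature datasets
#'
#' A feature dataset is a measurements-by-features matrix with per-row class
#' labels and per-column descriptors (`pair`, `kind`, `frequency`).
#'
#' @param matrix Numeric matrix, `n_measurements x n_features`.
#' @param labels Character vector of class labels, one per row.
#' @param descriptors Data frame with columns `pair`, `kind`, `frequency`,
#'   one row per feature column.
#' @return An object of class `tfr_dataset`.
#' @export
feature_dataset <- function(matrix, labels, descriptors) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(labels))
    stop("labels length must equal the number of rows")
  if (ncol(matrix) != nrow(descriptors))
    stop("descriptors must have one row per feature column")
  colnames(matrix) <- sprintf("%s_K%s_%gHz",
                              ifelse(descriptors$kind == "log_magnitude",
                                     "logmag", "arg"),
                              descriptors$pair, descriptors$frequency)
  structure(
    list(matrix = matrix, labels = as.character(labels),
         descriptors = descriptors),
    class = "tfr_dataset")
}

#' @rdname feature_dataset
#' @param x A `tfr_dataset`.
#' @param ... Ignored.
#' @export
print.tfr_dataset <- function(x, ...) {
  cat(sprintf("<tfr_dataset> %d measurements x %d features; classes: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s (%d)", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Frequency band
#'
#' Inclusive frequency interval used to restrict feature datasets. The four
#' canonical quarter-spectrum bands of a 0.125-10 Hz analysis are provided by
#' [canonical_bands()].
#'
#' @param f_lo Lower edge in Hz (inclusive, > 0).
#' @param f_hi Upper edge in Hz (inclusive, >= `f_lo`).
#' @return An object of class `tfr_band`.
#' @export
band <- function(f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo <= f_hi))
    stop("band requires 0 < f_lo <= f_hi, got [", f_lo, ", ", f_hi, "]")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "tfr_band")
}

#' @rdname band
#' @return For `canonical_bands()`: a named list of four `tfr_band` objects
#'   (`data_I` 0.125-2.5 Hz, `data_II` 2.625-5 Hz, `data_III` 5.125-7.5 Hz,
#'   `data_IV` 7.625-10 Hz).
#' @export
canonical_bands <- function() {
  list(data_I = band(0.125, 2.5), data_II = band(2.625, 5.0),
       data_III = band(5.125, 7.5), data_IV = band(7.625, 10.0))
}

#' Restrict a feature dataset to a frequency band
#'
#' Keeps exactly the feature columns whose descriptor frequency lies in
#' `[f_lo, f_hi]` (inclusive both ends); both log-magnitude and argument
#' features are retained and column order is preserved.
#'
#' @param ds A [feature_dataset()].
#' @param bnd A [band()].
#' @return A [feature_dataset()] with the selected columns.
#' @export
select_band <- function(ds, bnd) {
  stopifnot(inherits(ds, "tfr_dataset"), inherits(bnd, "tfr_band"))
  eps <- 1e-9
  keep <- ds$descriptors$frequency >= bnd$f_lo - eps &
    ds$descriptors$frequency <= bnd$f_hi + eps
  if (!any(keep))
    stop(sprintf("band [%g, %g] Hz selects no features", bnd$f_lo, bnd$f_hi))
  feature_dataset(ds$matrix[, keep, drop = FALSE], ds$labels,
                  ds$descriptors[keep, , drop = FALSE])
}

#' Build a feature dataset from a manifest
#'
#' Runs the full extraction pipeline for every manifest entry: read the
#' recording, cut the analysis window, FFT with mean subtraction and taper,
#' form the transfer function ratios, assemble the feature vector, and
#' optionally restrict to a band. Row order follows the manifest.
#'
#' @param m A [manifest()].
#' @param bnd Optional [band()] restriction.
#' @param log_base Magnitude log base, see [assemble_features()].
#' @param window Taper passed to [preprocess_and_fft()].
#' @param floor Denominator magnitude floor passed to [compute_tfrs()].
#' @return A [feature_dataset()].
#' @export
build_feature_dataset <- function(m, bnd = NULL, log_base = 10,
                                  window = "hanning", floor = 0) {
  stopifnot(inherits(m, "tfr_manifest"))
  rows <- vector("list", nrow(m$entries))
  descriptors <- NULL
  for (i in seq_len(nrow(m$entries))) {
    path <- m$entries$path[i]
    fv <- tryCatch({
      rec <- read_recording(path, m$sampling_rate,
                            label = m$entries$label[i])
      win <- extract_analysis_window(rec, m$window_start_s, m$window_length_s)
      assemble_features(
        compute_tfrs(preprocess_and_fft(win, window = window), floor = floor),
        log_base = log_base)
    }, error = function(e)
      stop("while processing ", path, ": ", conditionMessage(e),
           call. = FALSE))
    if (is.null(descriptors)) {
      descriptors <- fv$descriptors
    } else if (nrow(descriptors) != nrow(fv$descriptors)) {
      stop("recording ", path, " yields ", nrow(fv$descriptors),
           " features; expected ", nrow(descriptors))
    }
    rows[[i]] <- fv$values
  }
  ds <- feature_dataset(do.call(rbind, rows), m$entries$label, descriptors)
  if (!is.null(bnd)) ds <- select_band(ds, bnd) else ds
}

#' Read and write feature datasets
#'
#' The dataset is stored as three delimited text files sharing a stem:
#' `<stem>.matrix.csv` (full-precision feature matrix), `<stem>.labels.csv`,
#' and `<stem>.descriptors.csv`. Re-import is bit-exact.
#'
#' @param ds A [feature_dataset()].
#' @param stem Path stem (no extension).
#' @return `write_feature_dataset()`: `stem`, invisibly.
#'   `read_feature_dataset()`: the re-imported [feature_dataset()].
#' @export
write_feature_dataset <- function(ds, stem) {
  stopifnot(inherits(ds, "tfr_dataset"))
  rows <- apply(ds$matrix, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, paste0(stem, ".matrix.csv"))
  writeLines(c("label", ds$labels), paste0(stem, ".labels.csv"))
  utils::write.csv(ds$descriptors, paste0(stem, ".descriptors.csv"),
                   row.names = FALSE, quote = TRUE)
  invisible(stem)
}

#' @rdname write_feature_dataset
#' @export
read_feature_dataset <- function(stem) {
  lines <- readLines(paste0(stem, ".matrix.csv"), warn = FALSE)
  mat <- do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
  labels <- readLines(paste0(stem, ".labels.csv"), warn = FALSE)[-1L]
  desc <- utils::read.csv(paste0(stem, ".descriptors.csv"),
                          stringsAsFactors = FALSE)
  feature_dataset(mat, labels, desc)
}
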