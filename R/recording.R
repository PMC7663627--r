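#' Multichannel sensor recording
#'
#' A recording holds the raw time series of a multichannel chemical sensor
#' array: one column per channel, sampled at a fixed rate, optionally tagged
#' with the class label of the measured sample (the analyte).
#'
#' @param samples Numeric matrix, `n_samples x n_channels`. All values must be
#'   finite; at least 2 samples and 2 channels are required (transfer function
#'   ratios are defined between channel pairs).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param label Optional class name (analyte) of the measurement.
#' @param channel_names Optional character vector of channel names; defaults
#'   to `ch1, ch2, ...`.
#' @param metadata Optional named list of free-form metadata.
#'
#' @return An object of class `tfr_recording`: a list with elements
#'   `samples`, `sampling_rate`, `label`, `channel_names`, `metadata`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(320), 160, 2), sampling_rate = 20)
#' n_samples(rec)
recording <- function(samples, sampling_rate, label = NULL,
                      channel_names = NULL, metadata = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L)
    stop("a recording needs at least 2 samples, got ", nrow(samples))
  if (ncol(samples) < 2L)
    stop("a recording needs at least 2 channels, got ", ncol(samples))
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", ncol(samples), ")")
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         label = label, channel_names = as.character(channel_names),
         metadata = metadata),
    class = "tfr_recording")
}

#' @rdname recording
#' @param x A `tfr_recording`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname recording
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname recording
#' @param ... Ignored.
#' @export
print.tfr_recording <- function(x, ...) {
  cat(sprintf("<tfr_recording> %d samples x %d channels @ %g Hz (%.3g s)%s\n",
              n_samples(x), n_channels(x), x$sampling_rate,
              n_samples(x) / x$sampling_rate,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

# Detect comma vs tab delimiter from the header line.
detect_delimiter <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

is_time_column <- function(name) {
  tolower(trimws(name)) %in% c("time", "t", "time_s", "time (s)")
}

#' Read a recording from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected) with one header row and
#' one column per channel. An optional leading time column (header `time`,
#' `t` or `time_s`) is validated against the declared sampling rate and then
#' dropped: the device streams at a fixed rate, so the rate, not the time
#' stamps, is authoritative.
#'
#' @param path Path to the file.
#' @param sampling_rate Declared sampling rate in Hz.
#' @param label Optional class label attached to the returned recording.
#' @return A [recording()].
#' @export
read_recording <- function(path, sampling_rate, label = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("recording file has no data rows: ", path)
  delim <- detect_delimiter(lines[[1L]])
  header <- trimws(strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]])
  cells <- strsplit(lines[-1L], delim, fixed = TRUE)
  ncol_expect <- length(header)
  vals <- matrix(NA_real_, nrow = length(cells), ncol = ncol_expect)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    if (length(row) != ncol_expect)
      stop(sprintf("format error in %s, row %d: expected %d columns, found %d",
                   path, i, ncol_expect, length(row)))
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("format error in %s, row %d: non-numeric value '%s' in column '%s'",
                   path, i, trimws(row[bad]), header[bad]))
    }
    vals[i, ] <- v
  }
  has_time <- is_time_column(header[1L])
  if (has_time) {
    tt <- vals[, 1L]
    steps <- diff(tt)
    expected <- 1 / sampling_rate
    if (any(abs(steps - expected) > 1e-6))
      stop(sprintf(
        "format error in %s, row %d: irregular time step %.8g s (expected %.8g s at %g Hz)",
        path, which(abs(steps - expected) > 1e-6)[1L] + 1L, # +1: step i ends at row i+1
        steps[which(abs(steps - expected) > 1e-6)[1L]], expected, sampling_rate))
    vals <- vals[, -1L, drop = FALSE]
    header <- header[-1L]
  }
  if (ncol(vals) < 2L)
    stop("recording file must have at least 2 channel columns: ", path)
  recording(vals, sampling_rate, label = label, channel_names = header)
}

#' Write a recording to delimited text
#'
#' Writes a CSV with a `time` column and one column per channel, at full
#' double precision so that a write/read round trip is lossless to better
#' than 12 significant digits.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tfr_recording"))
  n <- n_samples(rec)
  tt <- (seq_len(n) - 1L) / rec$sampling_rate
  header <- paste(c("time", rec$channel_names), collapse = ",")
  body <- cbind(tt, rec$samples)
  rows <- apply(body, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write recording to ", path)
  invisible(path)
}

#' Extract the analysis window from a recording
#'
#' Free-hand measurements are disturbed at the beginning and end, so a fixed
#' interior window is used for analysis. The default downstream configuration
#' is an 8-second window starting at 2 s, which at 20 Hz gives the 160-sample
#' window on which all frequency arithmetic is based (0.125 Hz bin spacing).
#'
#' @param rec A [recording()].
#' @param start_s Window start in seconds (>= 0).
#' @param length_s Window length in seconds; `length_s * sampling_rate` must
#'   be integral.
#' @return A [recording()] holding the windowed slice; label and metadata are
#'   preserved.
#' @export
extract_analysis_window <- function(rec, start_s, length_s) {
  stopifnot(inherits(rec, "tfr_recording"))
  if (start_s < 0) stop("start_s must be >= 0")
  rate <- rec$sampling_rate
  n_win <- length_s * rate
  if (abs(n_win - round(n_win)) > 1e-9)
    stop("length_s * sampling_rate must be an integer number of samples, got ",
         n_win)
  n_win <- as.integer(round(n_win))
  first <- as.integer(round(start_s * rate)) + 1L
  last <- first + n_win - 1L
  if (last > n_samples(rec))
    stop(sprintf(
      "analysis window [%g, %g] s exceeds recording duration %g s",
      start_s, start_s + length_s, n_samples(rec) / rate))
  recording(rec$samples[first:last, , drop = FALSE], rate,
            label = rec$label, channel_names = rec$channel_names,
            metadata = rec$metadata)
}

#' Dataset manifests
#'
#' A manifest lists the recordings that form a dataset: one `(path, label)`
#' entry per measurement, the shared sampling rate, and the analysis window
#' applied before feature extraction. Manifests are stored as YAML.
#'
#' @param entries Data frame with columns `path` and `label`.
#' @param sampling_rate Sampling rate in Hz shared by all recordings.
#' @param window_start_s Analysis window start (seconds).
#' @param window_length_s Analysis window length (seconds);
#'   `window_length_s * sampling_rate` must be integral.
#' @return An object of class `tfr_manifest`.
#' @export
manifest <- function(entries, sampling_rate, window_start_s = 2,
                     window_length_s = 8) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "label") %in% names(entries)))
  if (any(!nzchar(entries$label) | is.na(entries$label)))
    stop("every manifest entry needs a non-empty label")
  if (anyDuplicated(entries$path))
    stop("manifest paths must be distinct; duplicated: ",
         entries$path[anyDuplicated(entries$path)])
  n_win <- window_length_s * sampling_rate
  if (abs(n_win - round(n_win)) > 1e-9)
    stop("window_length_s * sampling_rate must be an integer")
  structure(
    list(entries = entries[, c("path", "label")],
         sampling_rate = sampling_rate,
         window_start_s = window_start_s,
         window_length_s = window_length_s),
    class = "tfr_manifest")
}

#' @rdname manifest
#' @param path Path of the manifest YAML file.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  y <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(y$entries, function(e)
    data.frame(path = e$path, label = e$label, stringsAsFactors = FALSE)))
  # recording paths are stored relative to the manifest location
  entries$path <- file.path(dirname(path), entries$path)
  manifest(entries, y$sampling_rate, y$window_start_s, y$window_length_s)
}

#' @rdname manifest
#' @param m A `tfr_manifest`.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "tfr_manifest"))
  rel <- m$entries$path
  root <- dirname(path)
  pre <- paste0(root, "/")
  rel <- ifelse(startsWith(rel, pre), substring(rel, nchar(pre) + 1L), rel)
  y <- list(
    sampling_rate = m$sampling_rate,
    window_start_s = m$window_start_s,
    window_length_s = m$window_length_s,
    entries = lapply(seq_len(nrow(m$entries)), function(i)
      list(path = rel[i], label = m$entries$label[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}
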