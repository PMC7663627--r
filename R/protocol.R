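#' Idealized free-hand protocol waveform
#'
#' A free-hand measurement in which the device enters the sample headspace
#' `k` times is idealized as a binary concentration waveform: `2k + 1`
#' alternating segments of equal length over the analysis window, starting
#' and ending at 0 (outside the beaker). For the 8-second window this gives
#' segment lengths 8/3, 8/7, and 8/11 s for 1, 3, and 5 exposures.
#'
#' Segment boundaries fall on non-integer sample positions; sample `n`
#' (0-based) takes value 1 iff `floor(n * (2k + 1) / N)` is odd, i.e. each
#' sample belongs to the segment its index falls into.
#'
#' @param n_exposures Number of headspace entries `k` (>= 1).
#' @param duration_s Waveform duration in seconds (default 8).
#' @param sampling_rate Sampling rate in Hz (default 20);
#'   `duration_s * sampling_rate` must be integral.
#' @return An object of class `tfr_protocol`: list with `values` (0/1
#'   vector), `sampling_rate`, `n_exposures`, `segment_length_s`.
#' @export
#' @examples
#' w <- make_protocol_waveform(1)
#' sum(w$values)  # 53 one-valued samples
make_protocol_waveform <- function(n_exposures, duration_s = 8,
                                   sampling_rate = 20) {
  if (n_exposures < 1L) stop("n_exposures must be >= 1")
  n <- duration_s * sampling_rate
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * sampling_rate must be an integer, got ", n)
  n <- as.integer(round(n))
  segs <- 2L * n_exposures + 1L
  idx <- 0:(n - 1L)
  values <- as.numeric(floor(idx * segs / n) %% 2L == 1L)
  structure(
    list(values = values, sampling_rate = sampling_rate,
         n_exposures = as.integer(n_exposures),
         segment_length_s = duration_s / segs),
    class = "tfr_protocol")
}

#' Magnitude spectrum of a protocol waveform
#'
#' Unnormalized discrete Fourier transform of the raw binary values — no
#' taper and no mean subtraction (the mean affects only the DC bin, which is
#' not reported). Magnitudes are returned for bins `1 .. N/2`.
#'
#' @param w A `tfr_protocol` (or any numeric vector plus `sampling_rate`).
#' @param sampling_rate Required only when `w` is a bare numeric vector.
#' @return Data frame with columns `frequency` (Hz) and `magnitude`.
#' @export
waveform_spectrum <- function(w, sampling_rate = NULL) {
  if (inherits(w, "tfr_protocol")) {
    values <- w$values
    rate <- w$sampling_rate
  } else {
    values <- as.numeric(w)
    if (is.null(sampling_rate))
      stop("sampling_rate is required for a bare numeric waveform")
    rate <- sampling_rate
  }
  n <- length(values)
  if (n %% 2L != 0L) stop("waveform length must be even")
  x <- stats::fft(values)
  keep <- 2:(n / 2 + 1)
  data.frame(frequency = seq_len(n / 2) * rate / n,
             magnitude = Mod(x[keep]))
}

#' Sub-band spectral coverage of a protocol waveform
#'
#' Sums the DFT magnitudes over all bins in `[f_lo, f_hi]` (inclusive). The
#' default band, 0.125-1 Hz (8 bins for a 160-point, 20-Hz waveform), is the
#' frequency range that carries the sensing dynamics of nanomechanical
#' sensors; protocols with more exposures cover it more densely, which is why
#' they support better identification.
#'
#' @inheritParams waveform_spectrum
#' @param f_lo,f_hi Band edges in Hz, inclusive; must contain at least one
#'   bin and lie within (0, Nyquist].
#' @return The magnitude sum (a single number).
#' @export
#' @examples
#' band_magnitude_sum(make_protocol_waveform(5))  # about 117
band_magnitude_sum <- function(w, f_lo = 0.125, f_hi = 1.0,
                               sampling_rate = NULL) {
  sp <- waveform_spectrum(w, sampling_rate)
  eps <- 1e-9
  keep <- sp$frequency >= f_lo - eps & sp$frequency <= f_hi + eps
  if (!any(keep))
    stop(sprintf("band [%g, %g] Hz contains no frequency bins", f_lo, f_hi))
  sum(sp$magnitude[keep])
}
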