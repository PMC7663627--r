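#' Two-time-constant sensor kernel
#'
#' The response dynamics of a coated nanomechanical sensor channel are
#' modeled as a weighted sum of two first-order low-pass processes: gas
#' diffusion into the receptor film (time constant `tau_s`) and relaxation of
#' the film's elastic modulus (time constant `tau_r`), both typically in the
#' 1-100 s range. The impulse response is
#' `h(t) = gain * (a/tau_s * exp(-t/tau_s) + b/tau_r * exp(-t/tau_r))`
#' with `a + b = 1`, so the frequency response is
#' `H(f) = gain * (a / (1 + i*2*pi*f*tau_s) + b / (1 + i*2*pi*f*tau_r))`.
#'
#' @param a Weight of the diffusion branch; `b = 1 - a` is implied unless
#'   given.
#' @param tau_s Diffusion time constant, seconds (> 0).
#' @param tau_r Relaxation time constant, seconds (> 0).
#' @param gain Static gain, output units per unit concentration (non-zero).
#' @param b Weight of the relaxation branch; must satisfy `a + b = 1`.
#' @return An object of class `tfr_kernel`.
#' @export
kernel_params <- function(a, tau_s, tau_r, gain, b = 1 - a) {
  if (abs(a + b - 1) > 1e-12) stop("kernel weights must satisfy a + b = 1")
  if (tau_s <= 0 || tau_r <= 0) stop("time constants must be positive")
  if (gain == 0) stop("gain must be non-zero")
  structure(list(a = a, tau_s = tau_s, b = b, tau_r = tau_r, gain = gain),
            class = "tfr_kernel")
}

#' @rdname kernel_params
#' @param kp A `tfr_kernel`.
#' @param f Frequencies in Hz (may include 0).
#' @return For `kernel_frequency_response()`: complex vector `H(f)`.
#' @export
kernel_frequency_response <- function(kp, f) {
  kp$gain * (kp$a / (1 + 1i * 2 * pi * f * kp$tau_s) +
             kp$b / (1 + 1i * 2 * pi * f * kp$tau_r))
}

# Continuous impulse response sampled at times t (>= 0).
kernel_impulse_response <- function(kp, t) {
  kp$gain * (kp$a / kp$tau_s * exp(-t / kp$tau_s) +
             kp$b / kp$tau_r * exp(-t / kp$tau_r))
}

#' Ground-truth sensor model
#'
#' Holds one two-time-constant kernel per (channel, analyte) combination —
#' the simulator's ground truth, from which the analytic transfer function
#' ratios can be computed in closed form — plus the output noise level and
#' sampling rate.
#'
#' `default_model()` draws a random model: time constants log-uniform in
#' 1-100 s, branch weights uniform, and gains log-uniform in 0.5-2 per
#' (channel, analyte). Candidate models are rejected until every analyte pair
#' is separated by at least `min_separation` (root-mean-square difference of
#' the analytic TFR feature curves — log10 magnitude and argument over all
#' channel pairs — across the sub-1-Hz bins), guaranteeing distinct TFR
#' signatures.
#'
#' @param n_channels Number of sensor channels (default 4).
#' @param analytes Analyte names, or a count (default 4:
#'   water/hexane/methanol/acetone).
#' @param seed Integer seed; identical seeds give identical models.
#' @param noise_sigma Additive white Gaussian output noise level (default
#'   0.003, a few percent of a typical free-hand response peak).
#' @param sampling_rate Hz (default 20).
#' @param min_separation Minimum inter-analyte TFR distance (default 0.3).
#' @return An object of class `tfr_sensor_model`: list with `kernels` (a
#'   channels-by-analytes list matrix of `tfr_kernel`), `noise_sigma`,
#'   `sampling_rate`, `channels`, `analytes`.
#' @export
default_model <- function(n_channels = 4L, analytes = 4L, seed = 1L,
                          noise_sigma = 0.003, sampling_rate = 20,
                          min_separation = 0.3) {
  if (length(analytes) == 1L && is.numeric(analytes))
    analytes <- c("water", "hexane", "methanol", "acetone",
                  paste0("analyte", seq_len(max(0, analytes - 4))))[
                    seq_len(analytes)]
  analytes <- as.character(analytes)
  channels <- paste0("ch", seq_len(n_channels))
  set.seed(as.integer(seed))
  freqs <- seq(0.125, 1, by = 0.125)
  pairs <- channel_pairs(n_channels)
  draw <- function() {
    k <- matrix(vector("list", n_channels * length(analytes)),
                n_channels, length(analytes),
                dimnames = list(channels, analytes))
    for (ch in seq_len(n_channels)) for (an in seq_along(analytes)) {
      k[[ch, an]] <- kernel_params(
        a = stats::runif(1),
        tau_s = exp(stats::runif(1, log(1), log(100))),
        tau_r = exp(stats::runif(1, log(1), log(100))),
        gain = exp(stats::runif(1, log(0.5), log(2))))
    }
    k
  }
  signature <- function(kernels, an) {
    H <- vapply(seq_len(n_channels), function(ch)
      kernel_frequency_response(kernels[[ch, an]], freqs),
      complex(length(freqs)))
    unlist(lapply(seq_len(nrow(pairs)), function(p) {
      k <- H[, pairs[p, 1L]] / H[, pairs[p, 2L]]
      c(log10(Mod(k)), Arg(k))
    }))
  }
  for (attempt in seq_len(500L)) {
    kernels <- draw()
    sigs <- vapply(seq_along(analytes), function(an) signature(kernels, an),
                   numeric(2L * nrow(pairs) * length(freqs)))
    sep <- Inf
    for (i in seq_len(length(analytes) - 1L))
      for (j in (i + 1L):length(analytes))
        sep <- min(sep, sqrt(mean((sigs[, i] - sigs[, j])^2)))
    if (sep >= min_separation) {
      return(structure(
        list(kernels = kernels, noise_sigma = noise_sigma,
             sampling_rate = sampling_rate, channels = channels,
             analytes = analytes),
        class = "tfr_sensor_model"))
    }
  }
  stop("could not draw a model with inter-analyte TFR separation >= ",
       min_separation, " in 500 attempts")
}

#' Closed-form transfer function ratio of a sensor model
#'
#' The analytic oracle: `K[m,n](f) = H_m(f) / H_n(f)` evaluated from the
#' model's kernel parameters. Estimated TFRs from noiseless steady-periodic
#' simulator output must recover these values.
#'
#' @param model A `tfr_sensor_model`.
#' @param analyte Analyte name.
#' @param pair Integer pair `c(m, n)` of channel indices.
#' @param frequencies Frequencies in Hz.
#' @return Complex vector of ratios.
#' @export
analytic_tfr <- function(model, analyte, pair, frequencies) {
  stopifnot(inherits(model, "tfr_sensor_model"))
  if (!analyte %in% model$analytes) stop("unknown analyte: ", analyte)
  if (any(pair < 1L) || any(pair > length(model$channels)))
    stop("channel index out of range: ", paste(pair, collapse = ","))
  hm <- kernel_frequency_response(model$kernels[[pair[1L], analyte]],
                                  frequencies)
  hn <- kernel_frequency_response(model$kernels[[pair[2L], analyte]],
                                  frequencies)
  hm / hn
}

#' Simulate a multichannel sensor response
#'
#' Convolves a concentration input with every channel's kernel for the given
#' analyte and adds white Gaussian output noise.
#'
#' Two convolution modes:
#' \describe{
#'   \item{`transient`}{Causal convolution from rest: the continuous impulse
#'     response is sampled on the time grid and integrated against the input
#'     with trapezoidal weights. This is the realistic mode used by the
#'     dataset generator.}
#'   \item{`steady_periodic`}{The input is treated as one period of a
#'     periodic signal; each DFT bin of the input is multiplied by the exact
#'     frequency response `H(f)` at that bin. By the circular-convolution
#'     theorem the output spectrum is exactly `H(f) C(f)`, so TFRs estimated
#'     from the output (untapered) equal the analytic ratio to machine
#'     precision — the mode used for oracle validation.}
#' }
#'
#' @param model A `tfr_sensor_model`.
#' @param analyte Analyte name; becomes the recording label.
#' @param input Numeric concentration series sampled at the model rate.
#' @param mode `"transient"` or `"steady_periodic"`.
#' @param noise_sigma Noise level override; defaults to the model's.
#' @param seed Optional integer seed for the noise draw; `NULL` uses the
#'   current RNG state.
#' @return A [recording()] labeled with the analyte.
#' @export
simulate_response <- function(model, analyte, input,
                              mode = c("transient", "steady_periodic"),
                              noise_sigma = model$noise_sigma, seed = NULL) {
  stopifnot(inherits(model, "tfr_sensor_model"))
  mode <- match.arg(mode)
  if (!analyte %in% model$analytes) stop("unknown analyte: ", analyte)
  input <- as.numeric(input)
  n <- length(input)
  rate <- model$sampling_rate
  dt <- 1 / rate
  nc <- length(model$channels)
  out <- matrix(0, n, nc)
  for (ch in seq_len(nc)) {
    kp <- model$kernels[[ch, analyte]]
    if (mode == "transient") {
      h <- kernel_impulse_response(kp, (0:(n - 1L)) * dt)
      # trapezoid rule on [0, t_n]: half weight at both endpoints
      full <- stats::convolve(input, rev(h), type = "open")[seq_len(n)]
      y <- dt * (full - 0.5 * h[1L] * input - 0.5 * h * input[1L])
      out[, ch] <- y
    } else {
      f_pos <- (0:(n %/% 2)) * rate / n
      H <- kernel_frequency_response(kp, f_pos)
      Hfull <- complex(length.out = n)
      Hfull[seq_along(f_pos)] <- H
      if (n > 1L) {
        tail_idx <- (n %/% 2 + 2):n
        Hfull[tail_idx] <- Conj(Hfull[n - tail_idx + 2L])
      }
      if (n %% 2L == 0L) Hfull[n %/% 2 + 1L] <- Re(Hfull[n %/% 2 + 1L])
      out[, ch] <- Re(stats::fft(stats::fft(input) * Hfull,
                                 inverse = TRUE)) / n
    }
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    out <- out + matrix(stats::rnorm(n * nc, sd = noise_sigma), n, nc)
  }
  recording(out, rate, label = analyte, channel_names = model$channels)
}

#' Free-hand measurement simulation settings
#'
#' Parameters of the invented free-hand variability model layered on top of
#' the ideal binary protocol waveform: segment-boundary timing jitter (hand
#' motion), a random per-measurement amplitude scale (headspace concentration
#' differences), and first-order smoothing of the binary input (gas mixing at
#' the sensor). Transfer function ratios are invariant to all three by
#' linearity, so they add realism without corrupting the class structure.
#'
#' @param n_exposures Protocol: headspace entries per measurement (default 5).
#' @param duration_s Total measurement length in seconds (default 10; the
#'   protocol waveform spans the middle 8 s, leaving disturbed lead-in/out).
#' @param jitter Fractional timing perturbation of each segment boundary,
#'   uniform in `[-jitter, +jitter]` segment lengths; must be < 0.5
#'   (default 0.1).
#' @param amplitude_range Per-measurement concentration scale, drawn
#'   log-uniform from this range (default `c(0.5, 2)`).
#' @param mixing_tau First-order smoothing time constant in seconds emulating
#'   gas mixing (default 0.2; 0 disables).
#' @param lead_in_s Quiet time before the first exposure (default 1).
#' @param seed Integer seed controlling the whole generated dataset.
#' @return An object of class `tfr_sim_config`.
#' @export
simulation_config <- function(n_exposures = 5L, duration_s = 10,
                              jitter = 0.1, amplitude_range = c(0.5, 2),
                              mixing_tau = 0.2, lead_in_s = 1, seed = 1L) {
  if (jitter < 0 || jitter >= 0.5) stop("jitter must be in [0, 0.5)")
  if (mixing_tau < 0) stop("mixing_tau must be >= 0")
  structure(
    list(n_exposures = as.integer(n_exposures), duration_s = duration_s,
         jitter = jitter, amplitude_range = amplitude_range,
         mixing_tau = mixing_tau, lead_in_s = lead_in_s,
         seed = as.integer(seed)),
    class = "tfr_sim_config")
}

# One jittered, scaled, smoothed free-hand concentration input, drawn from
# the current RNG state. The nominal protocol spans 8 s after the lead-in.
freehand_input <- function(config, rate) {
  n_total <- as.integer(round(config$duration_s * rate))
  segs <- 2L * config$n_exposures + 1L
  seg_len <- 8 / segs
  bounds <- config$lead_in_s + seg_len * (0:segs)
  if (config$jitter > 0) {
    inner <- 2:segs  # first and last boundary stay put
    bounds[inner] <- bounds[inner] +
      stats::runif(length(inner), -config$jitter, config$jitter) * seg_len
  }
  tt <- (0:(n_total - 1L)) / rate
  x <- numeric(n_total)
  for (s in seq_len(segs)) {
    if (s %% 2L == 0L)  # even segments are inside the headspace
      x[tt >= bounds[s] & tt < bounds[s + 1L]] <- 1
  }
  x <- x * exp(stats::runif(1, log(config$amplitude_range[1L]),
                            log(config$amplitude_range[2L])))
  if (config$mixing_tau > 0) {
    alpha <- exp(-1 / (rate * config$mixing_tau))
    x <- stats::filter(x * (1 - alpha), alpha, method = "recursive")
    x <- as.numeric(x)
  }
  x
}

#' Generate a labeled synthetic free-hand dataset
#'
#' Emulates a measurement campaign: for each analyte, `n_per_analyte`
#' free-hand measurements are simulated (jittered protocol waveform, random
#' amplitude, mixing smoothing, transient convolution, output noise), written
#' as recording files, and listed in a manifest whose analysis window is the
#' central 8 s. Measurement order is randomized, as in a real campaign. The
#' whole dataset is reproducible from the config seed.
#'
#' @param model A `tfr_sensor_model`.
#' @param config A [simulation_config()].
#' @param n_per_analyte Measurements per analyte (default 30).
#' @param dir Output directory (created if missing).
#' @return The [manifest()], also written to `dir/manifest.yaml`.
#' @export
generate_dataset <- function(model, config, n_per_analyte = 30L, dir) {
  stopifnot(inherits(model, "tfr_sensor_model"),
            inherits(config, "tfr_sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  plan <- expand.grid(rep = seq_len(n_per_analyte), analyte = model$analytes,
                      stringsAsFactors = FALSE)
  plan <- plan[sample.int(nrow(plan)), ]  # randomized measurement order
  paths <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    x <- freehand_input(config, model$sampling_rate)
    rec <- simulate_response(model, plan$analyte[i], x, mode = "transient")
    paths[i] <- file.path(dir, sprintf("rec_%03d_%s.csv", i, plan$analyte[i]))
    write_recording(rec, paths[i])
  }
  m <- manifest(data.frame(path = paths, label = plan$analyte,
                           stringsAsFactors = FALSE),
                sampling_rate = model$sampling_rate,
                window_start_s = 2, window_length_s = 8)
  write_manifest(m, file.path(dir, "manifest.yaml"))
  m
}

#' Write and read a sensor model as structured text
#'
#' Serializes the ground-truth kernel parameters to YAML so oracle tests can
#' reload the model that generated a dataset.
#'
#' @param model A `tfr_sensor_model`.
#' @param path YAML file path.
#' @return `write_sensor_model()`: `path`, invisibly; `read_sensor_model()`:
#'   the model.
#' @export
write_sensor_model <- function(model, path) {
  stopifnot(inherits(model, "tfr_sensor_model"))
  kernels <- list()
  for (ch in model$channels) for (an in model$analytes) {
    kp <- model$kernels[[ch, an]]
    kernels[[paste(ch, an, sep = "|")]] <-
      list(a = kp$a, tau_s = kp$tau_s, b = kp$b, tau_r = kp$tau_r,
           gain = kp$gain)
  }
  yaml::write_yaml(list(channels = model$channels,
                        analytes = model$analytes,
                        noise_sigma = model$noise_sigma,
                        sampling_rate = model$sampling_rate,
                        kernels = kernels),
                   path, precision = 17L)
  invisible(path)
}

#' @rdname write_sensor_model
#' @export
read_sensor_model <- function(path) {
  y <- yaml::read_yaml(path)
  kernels <- matrix(vector("list", length(y$channels) * length(y$analytes)),
                    length(y$channels), length(y$analytes),
                    dimnames = list(y$channels, y$analytes))
  for (ch in y$channels) for (an in y$analytes) {
    kp <- y$kernels[[paste(ch, an, sep = "|")]]
    kernels[[ch, an]] <- kernel_params(a = kp$a, tau_s = kp$tau_s,
                                       tau_r = kp$tau_r, gain = kp$gain,
                                       b = kp$b)
  }
  structure(
    list(kernels = kernels, noise_sigma = y$noise_sigma,
         sampling_rate = y$sampling_rate, channels = y$channels,
         analytes = y$analytes),
    class = "tfr_sensor_model")
}
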