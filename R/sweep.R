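#' Exponential sweep specification
#'
#' Parameters of an exponential (logarithmic) sine sweep: power band
#' `f_start`..`f_end`, duration, sample rate. Defaults: 100 Hz to 10 kHz
#' over 21 s at 48 kHz, a band and length giving ample signal-to-noise
#' across the speech range.
#'
#' @param f_start,f_end Band edges in Hz, `0 < f_start < f_end <
#'   sample_rate/2`.
#' @param duration Sweep duration in s.
#' @param sample_rate Sample rate in Hz.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(f_start = 100, f_end = 10000, duration = 21,
                       sample_rate = 48000) {
  stopifnot(f_start > 0, f_end > f_start, f_end < sample_rate / 2,
            duration > 0)
  structure(list(f_start = f_start, f_end = f_end, duration = duration,
                 sample_rate = sample_rate), class = "sweep_spec")
}

#' Recording container
#'
#' A sampled waveform with its sample rate and a channel label
#' (`"sweep"`, `"P1"`, `"P3"` or `"Pref"`).
#'
#' @param samples Numeric vector of samples.
#' @param sample_rate Sample rate in Hz.
#' @param label Channel label.
#' @return A list of class `recording`.
#' @export
recording <- function(samples, sample_rate, label = "sweep") {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 label = as.character(label)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'> %d samples @ %g Hz (%.3f s)\n", x$label,
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Synthesize an exponential sine sweep
#'
#' `x(t) = sin(K (e^{t/L} - 1))` with `L = T / ln(f_end/f_start)` and
#' `K = 2 pi f_start L`, so the instantaneous frequency runs from
#' `f_start` at `t = 0` to `f_end` at `t = T` while the envelope stays at
#' unit amplitude. Each octave receives equal sweep time, which is what
#' makes harmonic distortion separable by deconvolution.
#'
#' @param spec A [sweep_spec()].
#' @return A [recording()] labeled `"sweep"`.
#' @export
farina_sweep <- function(spec = sweep_spec()) {
  fs <- spec$sample_rate
  t <- seq(0, spec$duration - 1 / fs, by = 1 / fs)
  L <- spec$duration / log(spec$f_end / spec$f_start)
  K <- 2 * pi * spec$f_start * L
  recording(sin(K * (exp(t / L) - 1)), fs, "sweep")
}

# exact inverse filter of the sweep in the frequency domain: conj(X) (the
# time-reversed sweep) with 1/|X|^2 amplitude compensation, regularized
# outside the power band (Kirkeby inversion)
sweep_inverse_spectrum <- function(sweep_fft, nfft, fs, f_start, f_end) {
  f <- (seq_len(nfft) - 1) * fs / nfft
  f_fold <- pmin(f, fs - f)
  pow <- Mod(sweep_fft)^2
  inband <- f_fold >= f_start & f_fold <= f_end
  eps_in <- 1e-8 * mean(pow[inband])
  eps_out <- max(pow)
  # smooth (half-cosine, log-amplitude) transition of the regularization
  # across the band edges limits pre-ringing of the inverse filter
  ramp <- rep(1, nfft)
  lo <- f_fold < f_start
  ramp[lo] <- 0.5 * (1 - cos(pi * pmax(f_fold[lo] / f_start * 2 - 1, 0)))
  hi <- f_fold > f_end
  ramp[hi] <- 0.5 * (1 + cos(pi * pmin(f_fold[hi] / f_end - 1, 0.2) / 0.2))
  eps <- exp(log(eps_out) + (log(eps_in) - log(eps_out)) * ramp)
  Conj(sweep_fft) / (pow + eps)
}

#' Deconvolve a recording against the excitation sweep
#'
#' Applies the amplitude-compensated time-reversed inverse sweep (computed
#' exactly in the frequency domain, regularized outside the sweep band) to
#' obtain the impulse response; harmonic-distortion images land at large
#' negative delays (the k-th harmonic arrives `L ln k` seconds early,
#' several seconds for the default sweep) and are removed by keeping only
#' `window` around the linear response. The default window of -50 ms to
#' +500 ms retains the band-limitation pre-ringing of the linear response
#' while excluding every distortion image. Returns the windowed impulse
#' response and the linear frequency response on the FFT grid.
#'
#' @param rec A [recording()] of the system's response to `sweep`.
#' @param sweep The excitation [recording()] (same sample rate).
#' @param window Keep-window around zero delay, in seconds
#'   `c(t_before, t_after)` with `t_before <= 0`.
#' @return A list with `impulse` (a [recording()]) and `frf` (a tibble
#'   `frequency_hz`, `frf` complex, `mag_db`) on the grid of the kept
#'   window length.
#' @export
deconvolve <- function(rec, sweep, window = c(-0.05, 0.5)) {
  if (rec$sample_rate != sweep$sample_rate) {
    stop(sprintf("sample-rate mismatch: recording %g Hz vs sweep %g Hz",
                 rec$sample_rate, sweep$sample_rate))
  }
  fs <- rec$sample_rate
  n <- max(length(rec$samples), length(sweep$samples))
  nfft <- stats::nextn(2 * n, 2)
  xf <- stats::fft(c(sweep$samples, numeric(nfft - length(sweep$samples))))
  yf <- stats::fft(c(rec$samples, numeric(nfft - length(rec$samples))))
  spec <- sweep_spec_guess(sweep)
  invf <- sweep_inverse_spectrum(xf, nfft, fs, spec$f_start, spec$f_end)
  ir_full <- Re(stats::fft(yf * invf, inverse = TRUE)) / nfft

  n_pre <- min(nfft, max(0L, ceiling(-window[1] * fs)))
  n_post <- min(nfft - n_pre, max(1L, floor(window[2] * fs)))
  kept <- c(ir_full[(nfft - n_pre + 1):nfft][seq_len(n_pre)],
            ir_full[seq_len(n_post)])
  nk <- stats::nextn(length(kept), 2)
  irf <- stats::fft(c(kept, numeric(nk - length(kept))))
  # undo the linear phase of the pre-window samples
  kidx <- seq_len(nk) - 1
  irf <- irf * exp(2i * pi * kidx * n_pre / nk)
  half <- seq_len(nk %/% 2 + 1)
  frf <- tibble::tibble(
    frequency_hz = (half - 1) * fs / nk,
    frf = irf[half],
    mag_db = 20 * log10(pmax(Mod(irf[half]), .Machine$double.xmin))
  )
  list(impulse = recording(kept, fs, paste0(rec$label, "_ir")), frf = frf)
}

# recover the band parameters of a sweep recording from its attributes if
# present, else assume the default band
sweep_spec_guess <- function(sweep) {
  sp <- attr(sweep, "sweep_spec")
  if (!is.null(sp)) return(sp)
  list(f_start = 100, f_end = 10000)
}

# frequency response -> impulse response on an FFT grid with half-cosine
# band-edge tapers, conjugate-symmetric extension. The result is circularly
# delayed by `shift_s` so that band-limitation pre-ringing stays contiguous
# with the main response instead of wrapping to the buffer end (the bulk
# delay is common to all channels and cancels in pressure ratios)
frf_to_impulse <- function(h_fun, nfft, fs, f_start, f_end, shift_s = 0.05) {
  half <- seq_len(nfft %/% 2 + 1)
  f <- (half - 1) * fs / nfft
  h <- complex(real = numeric(length(f)), imaginary = numeric(length(f)))
  pos <- f > 0
  h[pos] <- h_fun(f[pos])
  lo_edge <- c(f_start / 2, f_start)
  hi_edge <- c(f_end, min(1.2 * f_end, 0.98 * fs / 2))
  taper <- rep(1, length(f))
  lo <- f < lo_edge[2]
  taper[lo] <- 0.5 * (1 - cos(pi * pmax(f[lo] - lo_edge[1], 0) /
                                (lo_edge[2] - lo_edge[1])))
  hi <- f > hi_edge[1]
  taper[hi] <- 0.5 * (1 + cos(pi * pmin(f[hi] - hi_edge[1],
                                        hi_edge[2] - hi_edge[1]) /
                                (hi_edge[2] - hi_edge[1])))
  h <- h * taper
  m <- round(shift_s * fs)
  h <- h * exp(-2i * pi * f * m / fs)
  full <- c(h, Conj(h[(nfft %/% 2):2]))
  Re(stats::fft(full, inverse = TRUE)) / nfft
}

#' Simulate a full external-excitation measurement
#'
#' End-to-end virtual measurement of a resonator: the glottal pressure
#' `P1` (mouth open), blocked-mouth pressure `P3` and free-field reference
#' `Pref` are computed from the chain-matrix model ([pressure_set()]) on
#' an FFT grid, converted to impulse responses with band-edge tapers,
#' convolved with the excitation sweep, and overlaid with seeded white
#' Gaussian noise at the requested in-band SNR. Deconvolving the returned
#' recordings and forming `P1/P3` recovers the transfer function.
#'
#' @param m Vocal-tract `tm_series` builder: a function `f -> tm_series`
#'   evaluated on the FFT grid, or an [area_function()] (its chain matrix
#'   is used).
#' @param spec A [sweep_spec()].
#' @param snr_db In-band signal-to-noise ratio in dB (`Inf` for
#'   noiseless).
#' @param seed Integer seed for the noise (required when `snr_db` is
#'   finite).
#' @param distance Source distance in m (default 0.25).
#' @param constants An [acoustic_constants()] object.
#' @return A list of class `virtual_measurement` with [recording()]s
#'   `p1`, `p3`, `pref`, the `sweep`, and the `spec`.
#' @export
virtual_measurement <- function(m, spec = sweep_spec(), snr_db = Inf,
                                seed = NULL, distance = 0.25,
                                constants = acoustic_constants()) {
  clean <- virtual_measurement_clean(m, spec, distance, constants)
  add_measurement_noise(clean, snr_db, seed)
}

# deterministic part of virtual_measurement: noise-free recordings
virtual_measurement_clean <- function(m, spec = sweep_spec(),
                                      distance = 0.25,
                                      constants = acoustic_constants()) {
  fs <- spec$sample_rate
  nir <- stats::nextn(max(2^16, round(fs * 1.2)), 2)
  sweep <- farina_sweep(spec)
  attr(sweep, "sweep_spec") <- spec

  if (inherits(m, "area_function")) {
    af <- m
    m_fun <- function(f) area_function_matrix(af, f, constants)
    area_lips <- af$area_lips_m2
  } else {
    stop("m must be an area_function")
  }

  half <- seq_len(nir %/% 2 + 1)
  f <- (half - 1) * fs / nir
  fpos <- freq_grid(f[f > 0])
  mm <- m_fun(fpos)
  zr <- as_acoustic(piston_in_baffle(fpos, effective_radius(area_lips),
                                     constants), area_lips)
  nn <- environment_reciprocal(zr, mode = "monopole", distance = distance,
                               constants = constants)
  ps <- pressure_set(mm, nn, us = 1 + 0i, distance = distance,
                     constants = constants)

  make_channel <- function(vals, label) {
    lookup <- stats::approxfun(ps$frequency_hz, Re(vals), rule = 2)
    lookup_i <- stats::approxfun(ps$frequency_hz, Im(vals), rule = 2)
    h_fun <- function(fq) complex(real = lookup(fq), imaginary = lookup_i(fq))
    ir <- frf_to_impulse(h_fun, nir, fs, spec$f_start, spec$f_end)
    y <- fft_convolve(sweep$samples, ir)
    recording(y[seq_len(length(sweep$samples) + nir %/% 2)], fs, label)
  }
  out <- list(
    p1 = make_channel(ps$p1, "P1"),
    p3 = make_channel(ps$p3, "P3"),
    pref = make_channel(ps$pref, "Pref"),
    sweep = sweep, spec = spec
  )
  class(out) <- "virtual_measurement"
  out
}

# add seeded white Gaussian noise at an in-band SNR to the three channels
add_measurement_noise <- function(clean, snr_db = Inf, seed = NULL) {
  if (!is.finite(snr_db)) return(clean)
  if (is.null(seed)) stop("a seed is required for noisy measurements")
  spec <- clean$spec
  band_frac <- (spec$f_end - spec$f_start) / (spec$sample_rate / 2)
  out <- clean
  withr::local_seed(as.integer(seed))
  for (ch in c("p1", "p3", "pref")) {
    x <- out[[ch]]$samples
    p_sig <- mean(x^2)
    sd_noise <- sqrt(p_sig * 10^(-snr_db / 10) / band_frac)
    out[[ch]]$samples <- x + stats::rnorm(length(x), sd = sd_noise)
  }
  out
}

fft_convolve <- function(x, y) {
  nfft <- stats::nextn(length(x) + length(y) - 1, 2)
  xf <- stats::fft(c(x, numeric(nfft - length(x))))
  yf <- stats::fft(c(y, numeric(nfft - length(y))))
  Re(stats::fft(xf * yf, inverse = TRUE))[seq_len(length(x) + length(y) - 1)] / nfft
}

#' Recover the transfer function from a virtual (or real) measurement
#'
#' Deconvolves the `P1` and `P3` recordings against the sweep and forms
#' their ratio on the FFT grid, restricted to the requested band.
#'
#' @param vm A `virtual_measurement` (or a list with recordings `p1`,
#'   `p3` and `sweep`).
#' @param f_low,f_high Band to keep, in Hz.
#' @return A [transfer_function()] with provenance `"measured_ratio"`.
#' @export
measured_transfer_function <- function(vm, f_low = 150, f_high = 6000) {
  d1 <- deconvolve(vm$p1, vm$sweep)
  d3 <- deconvolve(vm$p3, vm$sweep)
  f <- d1$frf$frequency_hz
  keep <- f >= f_low & f <= f_high
  transfer_function(f[keep], d1$frf$frf[keep] / d3$frf$frf[keep],
                    provenance = "measured_ratio")
}

#' Repeated-seed virtual measurement study
#'
#' Computes the noise-free recordings once, then for each seed adds fresh
#' noise, recovers the transfer function and extracts formants. Used to
#' quantify formant stability against the measurement noise floor.
#'
#' @param af An [area_function()].
#' @param spec A [sweep_spec()].
#' @param snr_db In-band SNR in dB.
#' @param seeds Integer vector of noise seeds.
#' @param max_n Formants per seed.
#' @param ... Passed to `virtual_measurement_clean` (distance, constants).
#' @return A tibble with columns `seed`, `formant`, `frequency_hz`,
#'   `bandwidth_hz`, `amplitude_db`.
#' @export
virtual_measurement_study <- function(af, spec = sweep_spec(), snr_db = 60,
                                      seeds = 1:10, max_n = 4, ...) {
  clean <- virtual_measurement_clean(af, spec, ...)
  purrr::map_dfr(seeds, function(s) {
    vm <- add_measurement_noise(clean, snr_db, s)
    h <- measured_transfer_function(vm)
    ft <- find_formants(h, max_n = max_n)
    dplyr::mutate(tibble::as_tibble(ft), seed = s, .before = 1)
  })
}

# --- WAV I/O (32-bit float mono RIFF) --------------------------------------

#' Read and write recordings as 32-bit float WAV files
#'
#' Mono IEEE-float WAV, one channel per file; the channel label is taken
#' from / encoded in a `_p1` / `_p3` / `_pref` filename suffix where
#' present.
#'
#' @param rec A [recording()].
#' @param path File path.
#' @return `write_wav()`: `path` invisibly. `read_wav()`: a [recording()].
#' @export
write_wav <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  x <- rec$samples
  n_bytes <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4); readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file: ", path)
  fs <- NULL; fmt_code <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (fmt_code == 3 && bits == 32) {
        samples <- readBin(con, "double", n = size / 4, size = 4,
                           endian = "little")
      } else if (fmt_code == 1 && bits == 16) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           signed = TRUE, endian = "little") / 32768
      } else {
        stop("unsupported WAV encoding (need float32 or PCM16)")
      }
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  label <- "sweep"
  base <- tolower(basename(path))
  for (suf in c("p1", "p3", "pref")) {
    if (grepl(paste0("_", suf, "\\.wav$"), base)) {
      label <- toupper(substr(suf, 1, 1)) |> paste0(substring(suf, 2))
    }
  }
  recording(samples, fs, label)
}
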