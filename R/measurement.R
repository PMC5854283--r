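#' Transfer function container
#'
#' A per-frequency complex volume-velocity transfer function `H = U_lips /
#' U_glottis`, stored as a tibble with columns `frequency_hz`, `h`
#' (complex) and `provenance` (one of `"chain_matrix"`, `"fem"`,
#' `"measured_ratio"`, `"kitamura_ratio"`, `"pref_ratio"` recording how it
#' was obtained). `|H|` tends to 1 (0 dB) at low frequency for resonators
#' that are lossless at DC.
#'
#' @param frequencies_hz Frequency grid (Hz).
#' @param h Complex transfer-function values.
#' @param provenance How the function was obtained.
#' @return A tibble of class `transfer_function`.
#' @export
transfer_function <- function(frequencies_hz, h,
                              provenance = c("chain_matrix", "fem",
                                             "measured_ratio",
                                             "kitamura_ratio", "pref_ratio")) {
  provenance <- match.arg(provenance)
  f <- freq_grid(frequencies_hz)
  h <- as.complex(h)
  if (length(h) != length(f)) stop("h must match the grid length")
  if (any(!is.finite(Re(h)) | !is.finite(Im(h)))) {
    stop("transfer function must be finite at all grid points")
  }
  out <- tibble::tibble(frequency_hz = as.numeric(f), h = h,
                        provenance = provenance)
  class(out) <- c("transfer_function", class(out))
  out
}

#' Magnitude of a transfer function in dB
#' @param tf A [transfer_function()] (or any tibble with `h`).
#' @return Numeric vector `20 log10 |h|`.
#' @export
tf_mag_db <- function(tf) 20 * log10(Mod(tf$h))

#' Open-circuit pressure at the far port of an externally driven network
#'
#' For a volume-velocity source `Us` driving port 2 of a reciprocal network
#' `O` whose port 1 is left open (zero volume velocity, e.g. a microphone
#' at a closed glottal end), the pressure at port 1 is
#' `P = (o12 - o11 o22 / o21) Us`, which for `det O = 1` simplifies to
#' `-Us / o21`. Both forms are computed and compared: when they agree the
#' det-1 form is returned (it is free of the subtractive cancellation the
#' general form suffers when the matrix entries span many orders of
#' magnitude); a disagreement flags a non-reciprocal input with a warning
#' and falls back to the general form.
#'
#' @param net A `tm_series` (the network between the open port and the
#'   source).
#' @param us Complex source volume velocity per frequency (scalar recycled;
#'   default a flat unit spectrum).
#' @param check_tol Relative agreement required between the general and
#'   det-1 forms (default 1e-6; set `Inf` to force the general form for
#'   deliberately non-reciprocal nets).
#' @return Complex pressure vector, one value per frequency.
#' @export
open_circuit_pressure <- function(net, us = 1 + 0i, check_tol = 1e-6) {
  n <- length(net$frequency_hz)
  us <- as.complex(us)
  if (length(us) == 1L) us <- rep(us, n)
  if (length(us) != n) stop("us must match the grid length")
  if (any(us == 0)) stop("source volume velocity must be nonzero at all frequencies")
  bad <- which(net$m21 == 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "o21 is zero at %d grid point(s) (e.g. %s Hz): no coupling path between the ports",
      length(bad),
      paste(utils::head(net$frequency_hz[bad], 5), collapse = ", ")))
  }
  p_general <- (net$m12 - net$m11 * net$m22 / net$m21) * us
  if (!is.finite(check_tol)) return(p_general)
  p_det1 <- -us / net$m21
  rel <- Mod(p_general - p_det1) / pmax(Mod(p_det1), .Machine$double.xmin)
  if (max(rel) > check_tol) {
    warning(sprintf(
      "general and det-1 open-circuit forms disagree (max rel %.3g); network may not be reciprocal; using the general form",
      max(rel)))
    return(p_general)
  }
  p_det1
}

#' Reciprocal environment two-port with a prescribed input impedance
#'
#' Builds an environment matrix `N` (mouth side = port 1, source side =
#' port 2) constrained only by what physics demands of the exterior space:
#' `n11 / n21 = Zr` (its input impedance as seen from the mouth equals the
#' radiation impedance) and `det N = 1` (reciprocity). The remaining two
#' degrees of freedom `(g, h)` are free: `n11 = Zr g`, `n21 = g`,
#' `n22 = h`, `n12 = (Zr g h - 1) / g`.
#'
#' Two modes:
#' * `"random"`: `g`, `h` drawn per frequency from a seeded nonzero complex
#'   distribution. Exercising the blocked-pressure ratio over many random
#'   environments demonstrates that the recovered transfer function does
#'   not depend on the exterior space at all.
#' * `"monopole"`: a physically flavored point-source environment at
#'   distance `d`: `g = 4 pi d e^{j k d} / (j omega rho)`, `h = e^{j k d}`.
#'
#' @param zr An [impedance_spectrum()] in the *acoustic* convention (the
#'   radiation load of the mouth opening).
#' @param mode `"random"` or `"monopole"`.
#' @param seed Integer seed (required for `"random"`).
#' @param distance Source distance in m for `"monopole"` (default 0.25,
#'   far enough to avoid near-field effects on the resonator).
#' @param constants An [acoustic_constants()] object.
#' @return A `tm_series` labeled `"environment"`.
#' @export
environment_reciprocal <- function(zr, mode = c("monopole", "random"),
                                   seed = NULL, distance = 0.25,
                                   constants = acoustic_constants()) {
  mode <- match.arg(mode)
  if (imp_convention(zr) != "acoustic") {
    stop("zr must be in the acoustic convention (Pa s/m^3); see as_acoustic()")
  }
  f <- zr$frequency_hz
  n <- length(f)
  if (mode == "random") {
    if (is.null(seed)) stop("random mode requires a seed")
    g <- h <- NULL
    withr::local_seed(as.integer(seed))
    draw_nonzero <- function() {
      z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
      small <- Mod(z) < 1e-3
      z[small] <- z[small] + (1e-3 + 0i)
      z
    }
    # scale g so |Zr g| = O(1): keeps the determinant cancellation at
    # machine epsilon without restricting the environment's freedom
    g <- draw_nonzero() / pmax(Mod(zr$z), 1)
    h <- draw_nonzero()
  } else {
    stopifnot(distance > 0)
    k <- wavenumber(f, constants)
    w <- omega(f)
    g <- 4 * pi * distance * exp(1i * k * distance) /
      (1i * w * constants$density)
    h <- exp(1i * k * distance)
  }
  tm_series(f,
            m11 = zr$z * g,
            m12 = (zr$z * g * h - 1) / g,
            m21 = g,
            m22 = h,
            label = "environment")
}

#' Volume-velocity transfer function from the blocked-pressure ratio
#'
#' The measurement identity at the core of the package: excite the
#' resonator externally, measure the pressure `P1` at the closed glottal
#' end with the mouth open, block the mouth and measure the pressure `P3`
#' right in front of it; then
#' \deqn{P_1 / P_3 = \frac{1}{m_{21} Z_r + m_{22}} = H = U_2/U_1,}
#' the volume-velocity transfer function of the resonator — independent of
#' the source spectrum `Us` (it cancels in the ratio) and of every detail
#' of the exterior space beyond its input impedance `Zr`.
#'
#' @param m Vocal-tract `tm_series` (glottis = port 1, mouth = port 2).
#' @param n Environment `tm_series` (see [environment_reciprocal()]).
#' @param us Source volume velocity (scalar or per-frequency; cancels).
#' @return A [transfer_function()] with provenance `"measured_ratio"`.
#' @seealso [transfer_direct()] for the direct chain-matrix evaluation.
#' @export
blocked_ratio_transfer <- function(m, n, us = 1 + 0i) {
  check_same_grid(m$frequency_hz, n$frequency_hz, "vocal tract M", "environment N")
  o <- cascade(m, n, label = "joint")
  p1 <- open_circuit_pressure(o, us)
  p3 <- open_circuit_pressure(n, us)
  # when both networks are reciprocal the ratio simplifies to n21/o21, in
  # which the source spectrum cancels identically (not just to rounding)
  det_ok <- max(Mod(tm_det(m) - 1)) < 1e-6 && max(Mod(tm_det(n) - 1)) < 1e-6
  h <- if (det_ok) n$m21 / o$m21 else p1 / p3
  transfer_function(m$frequency_hz, h, provenance = "measured_ratio")
}

#' Volume-velocity transfer function directly from the chain matrix
#'
#' `H = 1 / (m21 Zr + m22)`: the transfer function of a resonator with
#' chain matrix `M` terminated by the radiation load `Zr` at the mouth.
#'
#' @param m Vocal-tract `tm_series`.
#' @param zr Radiation impedance as an *acoustic* [impedance_spectrum()]
#'   (use `impedance_spectrum(grid, 0)` for an ideal open end).
#' @return A [transfer_function()] with provenance `"chain_matrix"`.
#' @export
transfer_direct <- function(m, zr) {
  check_same_grid(m$frequency_hz, zr$frequency_hz, "vocal tract M", "Zr")
  if (imp_convention(zr) != "acoustic") {
    stop("zr must be in the acoustic convention (Pa s/m^3); see as_acoustic()")
  }
  den <- m$m21 * zr$z + m$m22
  bad <- which(den == 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "m21 Zr + m22 vanishes at %g Hz: undamped pole on the grid; shift the grid",
      m$frequency_hz[bad[1]]))
  }
  transfer_function(m$frequency_hz, 1 / den, provenance = "chain_matrix")
}

#' Convenience: chain-matrix transfer function of an area function
#'
#' Builds the tract matrix, the piston radiation load for the lips area,
#' and returns `transfer_direct()`.
#'
#' @param af An [area_function()].
#' @param frequencies_hz Frequency grid (Hz).
#' @param constants An [acoustic_constants()] object.
#' @return A [transfer_function()] with provenance `"chain_matrix"`.
#' @examples
#' h <- chain_transfer_function(schwa_tube(), default_grid())
#' @export
chain_transfer_function <- function(af, frequencies_hz,
                                    constants = acoustic_constants()) {
  f <- freq_grid(frequencies_hz)
  m <- area_function_matrix(af, f, constants)
  zr <- piston_in_baffle(f, effective_radius(af$area_lips_m2), constants)
  transfer_direct(m, as_acoustic(zr, af$area_lips_m2))
}

#' Glottal pressure predicted by the single-measurement approximation
#'
#' An earlier external-excitation approach took the glottal pressure alone
#' as a stand-in for the transfer function, via
#' `P1 = [1 + Zr/Z0] Ps H`. The bracket tilts the spectrum upward because
#' `|Zr|` grows with frequency, so `P1` tracks `H` in formant positions but
#' not in spectral balance. This function evaluates that prediction and
#' returns the tilt factor alongside.
#'
#' @param h A [transfer_function()].
#' @param zr Radiation impedance (acoustic convention) on the same grid.
#' @param z0 Characteristic impedance (acoustic convention) on the same
#'   grid, typically `rho c / A_lips`.
#' @param ps Source pressure spectrum (scalar recycled; default 1).
#' @return A tibble with columns `frequency_hz`, `p1` (complex), `tilt_db`
#'   (`20 log10 |1 + Zr/Z0|`).
#' @export
kitamura_prediction <- function(h, zr, z0, ps = 1 + 0i) {
  check_same_grid(h$frequency_hz, zr$frequency_hz, "H", "Zr")
  check_same_grid(h$frequency_hz, z0$frequency_hz, "H", "Z0")
  if (imp_convention(zr) != "acoustic" || imp_convention(z0) != "acoustic") {
    stop("zr and z0 must both be in the acoustic convention")
  }
  n <- length(h$frequency_hz)
  ps <- as.complex(ps)
  if (length(ps) == 1L) ps <- rep(ps, n)
  tilt <- 1 + zr$z / z0$z
  tibble::tibble(frequency_hz = h$frequency_hz,
                 p1 = tilt * ps * h$h,
                 tilt_db = 20 * log10(Mod(tilt)))
}

#' Bias of normalizing by the free-field reference pressure
#'
#' Normalizing the glottal pressure by the free-field pressure `Pref`
#' (measured with the resonator absent) does *not* recover the transfer
#' function: `P1/Pref = H * Us / (Us - n11 U2)`, where `U2` is the volume
#' velocity through the (now unobstructed) mouth position in the free
#' field. The bias factor depends on the source and drifts upward with
#' frequency.
#'
#' With the model absent, `U2` is the volume velocity the free-field
#' monopole wave carries through the (now empty) mouth-aperture disc:
#' `U2 = A_lips * v_r(d)`, with the radial particle velocity
#' `v_r = (P_ff / rho c) (1 + 1/(j k d))`. The bias magnitude then scales
#' like `|n11 U2 / Us| ~ |Zr| / Z0`, which grows with frequency — the
#' upward spectral drift that the blocked-mouth normalization avoids.
#' (Evaluating the environment two-port itself against the free-field
#' pressure instead would return `|bias| = 1` identically, because a pure
#' point-source two-port scatters nothing.)
#'
#' @param m Vocal-tract `tm_series`.
#' @param n Environment `tm_series`, built in `"monopole"` mode so that the
#'   free-field pressure at the mouth position is defined.
#' @param us Source volume velocity (scalar or per frequency).
#' @param distance Source distance in m used when building `n`.
#' @param constants An [acoustic_constants()] object.
#' @param area_lips Mouth aperture area in m^2 for the free-field `U2`
#'   (default: the aperture of the canonical uniform tube).
#' @param u2 Optional override for the mouth-position free-field volume
#'   velocity (e.g. `0` to model a blocked mouth, which removes the bias).
#' @return A tibble with columns `frequency_hz`, `ratio` (complex
#'   `P1/Pref`), `h` (the true transfer function), `bias` (complex factor),
#'   `bias_db`.
#' @export
pref_bias <- function(m, n, us = 1 + 0i, distance = 0.25,
                      constants = acoustic_constants(),
                      area_lips = pi * 0.0138^2, u2 = NULL) {
  check_same_grid(m$frequency_hz, n$frequency_hz, "vocal tract M", "environment N")
  f <- m$frequency_hz
  len <- length(f)
  us <- as.complex(us)
  if (length(us) == 1L) us <- rep(us, len)
  zr <- impedance_spectrum(f, n$m11 / n$m21, convention = "acoustic")
  h <- transfer_direct(m, zr)
  if (is.null(u2)) {
    # model absent: free-field monopole pressure at the mouth position and
    # the flow it carries through the empty mouth-aperture disc
    k <- wavenumber(f, constants)
    w <- omega(f)
    pref_ff <- 1i * w * constants$density * us *
      exp(-1i * k * distance) / (4 * pi * distance)
    rhoc <- constants$density * constants$speed_of_sound
    v_r <- pref_ff / rhoc * (1 + 1 / (1i * k * distance))
    u2 <- area_lips * v_r
  } else {
    u2 <- as.complex(u2)
    if (length(u2) == 1L) u2 <- rep(u2, len)
  }
  den <- us - n$m11 * u2
  bad <- which(den == 0)
  if (length(bad) > 0) {
    stop(sprintf("Us - n11 U2 vanishes at %g Hz; bias undefined there",
                 f[bad[1]]))
  }
  bias <- us / den
  tibble::tibble(frequency_hz = f, ratio = h$h * bias, h = h$h,
                 bias = bias, bias_db = 20 * log10(Mod(bias)))
}

#' Full simulated pressure set for a measurement scenario
#'
#' Computes the three spectra the method records: `P1` (glottal pressure,
#' mouth open), `P3` (pressure in front of the blocked mouth) and `Pref`
#' (free-field pressure with the resonator absent), for a tract `M` driven
#' through a monopole environment at the given distance.
#'
#' @inheritParams pref_bias
#' @return A tibble with complex columns `p1`, `p3`, `pref` and
#'   `frequency_hz`.
#' @export
pressure_set <- function(m, n, us = 1 + 0i, distance = 0.25,
                         constants = acoustic_constants()) {
  check_same_grid(m$frequency_hz, n$frequency_hz, "vocal tract M", "environment N")
  f <- m$frequency_hz
  len <- length(f)
  us <- as.complex(us)
  if (length(us) == 1L) us <- rep(us, len)
  o <- cascade(m, n, label = "joint")
  p1 <- open_circuit_pressure(o, us)
  p3 <- open_circuit_pressure(n, us)
  k <- wavenumber(f, constants)
  w <- omega(f)
  pref <- 1i * w * constants$density * us *
    exp(-1i * k * distance) / (4 * pi * distance)
  tibble::tibble(frequency_hz = f, p1 = p1, p3 = p3, pref = pref)
}
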