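#' Transmission-matrix series
#'
#' A per-frequency 2x2 complex transmission (chain / ABCD) matrix relating
#' pressure and volume velocity at two ports, `(P_in, U_in) = M (P_out,
#' U_out)`. Stored as a tibble with one row per frequency and complex columns
#' `m11` (dimensionless), `m12` (acoustic impedance, Pa s/m^3), `m21`
#' (acoustic admittance, m^3/(Pa s)) and `m22` (dimensionless). Reciprocal
#' elements have unit determinant at every frequency.
#'
#' The port convention used throughout: for a vocal-tract matrix `M`, port 1
#' is the glottis side and port 2 the mouth side; for an environment matrix
#' `N`, port 1 is the mouth side and port 2 the source side. Volume velocity
#' is positive in the glottis -> mouth -> source direction, so the joint
#' glottis-to-source matrix is the ordinary product `M %_% N` (see
#' [cascade()]).
#'
#' @param frequencies_hz Frequency grid (Hz), strictly increasing, > 0.
#' @param m11,m12,m21,m22 Complex vectors, one value per frequency (scalars
#'   are recycled).
#' @param label Optional label, e.g. `"vocal_tract"`, `"environment"`,
#'   `"joint"`.
#' @return A tibble of class `tm_series` with columns `frequency_hz`, `m11`,
#'   `m12`, `m21`, `m22`.
#' @seealso [cascade()], [reciprocity_deviation()], [uniform_tube_matrix()]
#' @export
tm_series <- function(frequencies_hz, m11, m12, m21, m22, label = "other") {
  f <- freq_grid(frequencies_hz)
  n <- length(f)
  rec <- function(x) {
    x <- as.complex(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop("matrix entries must match the grid length")
    x
  }
  out <- tibble::tibble(
    frequency_hz = as.numeric(f),
    m11 = rec(m11), m12 = rec(m12), m21 = rec(m21), m22 = rec(m22)
  )
  attr(out, "label") <- label
  class(out) <- c("tm_series", class(out))
  out
}

#' Identity two-port on a grid
#' @param frequencies_hz Frequency grid (Hz).
#' @return A `tm_series` that leaves (P, U) unchanged.
#' @export
tm_identity <- function(frequencies_hz) {
  tm_series(frequencies_hz, 1 + 0i, 0i, 0i, 1 + 0i, label = "identity")
}

#' Cascade (chain) two two-port series
#'
#' Per-frequency matrix product `a %*% b`, the joint matrix of `a` followed
#' by `b` (output ports of `a` connected to input ports of `b`).
#'
#' @param a,b `tm_series` objects on the same frequency grid.
#' @param label Label for the result (default `"joint"`).
#' @return A `tm_series` with `det(result) = det(a) * det(b)` per frequency.
#' @examples
#' g <- default_grid(step = 100)
#' cst <- acoustic_constants()
#' m <- uniform_tube_matrix(tube_section(0.17, 5.98e-4), g, cst)
#' identical_m <- cascade(tm_identity(g), m)
#' @export
cascade <- function(a, b, label = "joint") {
  check_same_grid(a$frequency_hz, b$frequency_hz, "a", "b")
  tm_series(
    a$frequency_hz,
    m11 = a$m11 * b$m11 + a$m12 * b$m21,
    m12 = a$m11 * b$m12 + a$m12 * b$m22,
    m21 = a$m21 * b$m11 + a$m22 * b$m21,
    m22 = a$m21 * b$m12 + a$m22 * b$m22,
    label = label
  )
}

#' Determinant and reciprocity deviation of a transmission-matrix series
#'
#' Acoustic two-ports built from passive reciprocal elements satisfy
#' `det M = 1` at every frequency; `reciprocity_deviation()` reports
#' `|det - 1|` per frequency as a quick diagnostic of whether a constructed
#' or measured series is physically consistent.
#'
#' @param m A `tm_series`.
#' @return `tm_det()`: complex vector of per-frequency determinants.
#'   `reciprocity_deviation()`: a tibble with columns `frequency_hz`,
#'   `deviation` (`|det - 1|`), plus an attribute `max_deviation`.
#' @export
tm_det <- function(m) m$m11 * m$m22 - m$m12 * m$m21

#' @rdname tm_det
#' @export
reciprocity_deviation <- function(m) {
  dev <- Mod(tm_det(m) - 1)
  out <- tibble::tibble(frequency_hz = m$frequency_hz, deviation = dev)
  attr(out, "max_deviation") <- max(dev)
  out
}

#' Characteristic impedance of a plane wave in a duct
#'
#' `Z0 = rho * c / A`, the (acoustic-convention, Pa s/m^3) characteristic
#' impedance of a plane wave in a duct of cross-sectional area `A`. It is
#' real and frequency independent; the returned spectrum is constant over
#' the grid.
#'
#' @param area Cross-sectional area in m^2, > 0.
#' @param constants An [acoustic_constants()] object.
#' @param frequencies_hz Frequency grid the constant spectrum is laid out on.
#' @return An [impedance_spectrum()] with `convention = "acoustic"`.
#' @examples
#' z0 <- characteristic_impedance(5.98e-4, frequencies_hz = default_grid())
#' head(z0$z) # about 6.88e5 Pa s/m^3
#' @export
characteristic_impedance <- function(area, constants = acoustic_constants(),
                                     frequencies_hz = default_grid()) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0) {
    stop("area must be a single positive number (m^2)")
  }
  z0 <- constants$density * constants$speed_of_sound / area
  impedance_spectrum(frequencies_hz, rep(complex(real = z0), length(frequencies_hz)),
                     convention = "acoustic")
}

#' Write a transmission-matrix series to CSV
#'
#' Columns: `frequency_hz, re_m11, im_m11, re_m12, im_m12, re_m21, im_m21,
#' re_m22, im_m22`.
#'
#' @param m A `tm_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tm_csv <- function(m, path) {
  out <- tibble::tibble(
    frequency_hz = m$frequency_hz,
    re_m11 = Re(m$m11), im_m11 = Im(m$m11),
    re_m12 = Re(m$m12), im_m12 = Im(m$m12),
    re_m21 = Re(m$m21), im_m21 = Im(m$m21),
    re_m22 = Re(m$m22), im_m22 = Im(m$m22)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a transmission-matrix series from CSV written by [write_tm_csv()]
#' @param path Input file path.
#' @param label Label for the series.
#' @return A `tm_series`.
#' @export
read_tm_csv <- function(path, label = "other") {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  tm_series(d$frequency_hz,
            complex(real = d$re_m11, imaginary = d$im_m11),
            complex(real = d$re_m12, imaginary = d$im_m12),
            complex(real = d$re_m21, imaginary = d$im_m21),
            complex(real = d$re_m22, imaginary = d$im_m22),
            label = label)
}
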