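#' Impedance spectrum
#'
#' A per-frequency complex impedance with an explicit convention flag:
#' `"acoustic"` impedance relates pressure to volume velocity (Pa s/m^3);
#' `"specific"` impedance relates pressure to particle velocity (Pa s/m).
#' The two differ by the cross-sectional (or piston) area, and the flag is
#' carried as a column so that no conversion ever happens silently.
#'
#' @param frequencies_hz Frequency grid (Hz).
#' @param z Complex impedance values, one per frequency (scalar recycled).
#' @param convention `"acoustic"` or `"specific"`.
#' @return A tibble of class `impedance_spectrum` with columns
#'   `frequency_hz`, `z`, `convention`.
#' @seealso [as_acoustic()], [as_specific()], [piston_in_baffle()]
#' @export
impedance_spectrum <- function(frequencies_hz, z,
                               convention = c("acoustic", "specific")) {
  convention <- match.arg(convention)
  f <- freq_grid(frequencies_hz)
  z <- as.complex(z)
  if (length(z) == 1L) z <- rep(z, length(f))
  if (length(z) != length(f)) stop("impedance values must match the grid length")
  out <- tibble::tibble(frequency_hz = as.numeric(f), z = z,
                        convention = convention)
  class(out) <- c("impedance_spectrum", class(out))
  out
}

imp_convention <- function(zs) {
  conv <- unique(zs$convention)
  if (length(conv) != 1L) stop("mixed impedance conventions in one spectrum")
  conv
}

#' Convert between specific and acoustic impedance conventions
#'
#' Dividing a specific impedance (Pa s/m) by the port area gives the
#' acoustic impedance (Pa s/m^3) of the same load, and vice versa. The
#' round trip is exact.
#'
#' @param zs An [impedance_spectrum()].
#' @param area Port area in m^2, > 0.
#' @return An [impedance_spectrum()] in the requested convention.
#' @export
as_acoustic <- function(zs, area) {
  stopifnot(area > 0)
  if (imp_convention(zs) == "acoustic") return(zs)
  impedance_spectrum(zs$frequency_hz, zs$z / area, convention = "acoustic")
}

#' @rdname as_acoustic
#' @export
as_specific <- function(zs, area) {
  stopifnot(area > 0)
  if (imp_convention(zs) == "specific") return(zs)
  impedance_spectrum(zs$frequency_hz, zs$z * area, convention = "specific")
}

#' Write / read an impedance spectrum as CSV
#'
#' Columns: `frequency_hz, re, im, convention`.
#' @param zs An [impedance_spectrum()].
#' @param path File path.
#' @return `path` invisibly (write); an `impedance_spectrum` (read).
#' @export
write_impedance_csv <- function(zs, path) {
  readr::write_csv(tibble::tibble(frequency_hz = zs$frequency_hz,
                                  re = Re(zs$z), im = Im(zs$z),
                                  convention = zs$convention), path)
  invisible(path)
}

#' @rdname write_impedance_csv
#' @export
read_impedance_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  impedance_spectrum(d$frequency_hz, complex(real = d$re, imaginary = d$im),
                     convention = unique(d$convention))
}
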