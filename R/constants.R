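#' Acoustic constants
#'
#' Bundle the speed of sound and ambient air density used throughout the
#' package. The defaults are the standard values for air at 20 degrees
#' Celsius: c = 343 m/s and rho = 1.20 kg/m^3.
#'
#' @param speed_of_sound Speed of sound in m/s. Must be positive.
#' @param density Ambient density in kg/m^3. Must be positive.
#' @param temperature_note Free-text note recording the temperature the
#'   constants correspond to.
#'
#' @return A list of class `acoustic_constants` with elements
#'   `speed_of_sound`, `density` and `temperature_note`.
#' @examples
#' cst <- acoustic_constants()
#' cst$speed_of_sound # 343
#' @export
acoustic_constants <- function(speed_of_sound = 343.0,
                               density = 1.20,
                               temperature_note = "air at 20 degrees Celsius") {
  stopifnot(is.numeric(speed_of_sound), length(speed_of_sound) == 1L,
            is.finite(speed_of_sound), speed_of_sound > 0,
            is.numeric(density), length(density) == 1L,
            is.finite(density), density > 0)
  structure(
    list(speed_of_sound = as.numeric(speed_of_sound),
         density = as.numeric(density),
         temperature_note = as.character(temperature_note)),
    class = "acoustic_constants"
  )
}

#' @export
print.acoustic_constants <- function(x, ...) {
  cat("<acoustic_constants> c =", x$speed_of_sound, "m/s, rho =",
      x$density, "kg/m^3 (", x$temperature_note, ")\n")
  invisible(x)
}

#' Frequency grid
#'
#' An explicit, strictly increasing sequence of evaluation frequencies in Hz.
#' DC (0 Hz) is excluded: several plane-wave and radiation formulas are 0/0
#' there, so low-frequency limits are asserted at the lowest grid frequency
#' instead (3 Hz by default).
#'
#' @param frequencies_hz Numeric vector of frequencies in Hz, strictly
#'   increasing, all > 0.
#' @return A numeric vector of class `freq_grid`.
#' @examples
#' g <- freq_grid(seq(3, 6000, by = 3))
#' @export
freq_grid <- function(frequencies_hz) {
  f <- as.numeric(frequencies_hz)
  if (length(f) == 0L) stop("frequency grid must be nonempty")
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("all grid frequencies must be finite and > 0 (DC is excluded)")
  }
  if (any(diff(f) <= 0)) stop("frequency grid must be strictly increasing")
  structure(f, class = "freq_grid")
}

#' Default evaluation grid: 3 Hz resolution from 3 Hz to 6 kHz
#' @param step Grid step in Hz (default 3).
#' @param f_max Upper band edge in Hz (default 6000).
#' @return A `freq_grid`.
#' @export
default_grid <- function(step = 3, f_max = 6000) {
  freq_grid(seq(step, f_max, by = step))
}

#' Angular frequency and wave number helpers
#'
#' `omega()` returns 2*pi*f; `wavenumber()` returns omega/c for the given
#' constants.
#'
#' @param frequencies_hz Frequencies in Hz.
#' @param constants An [acoustic_constants()] object.
#' @return Numeric vector.
#' @export
omega <- function(frequencies_hz) 2 * pi * as.numeric(frequencies_hz)

#' @rdname omega
#' @export
wavenumber <- function(frequencies_hz, constants = acoustic_constants()) {
  omega(frequencies_hz) / constants$speed_of_sound
}

# internal: check two objects share one grid (exact match expected; these are
# value sequences, not specs, so interoperating grids must be built once)
check_same_grid <- function(fa, fb, what_a = "a", what_b = "b") {
  fa <- as.numeric(fa); fb <- as.numeric(fb)
  if (length(fa) != length(fb) || any(fa != fb)) {
    stop(sprintf(
      "frequency grid mismatch between '%s' (%d pts, %g..%g Hz) and '%s' (%d pts, %g..%g Hz)",
      what_a, length(fa), min(fa), max(fa),
      what_b, length(fb), min(fb), max(fb)))
  }
  invisible(fa)
}
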