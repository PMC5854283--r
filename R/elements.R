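#' Tube section
#'
#' One piecewise-cylindrical section of an acoustic tube, described by its
#' length, cross-sectional area and wall impedance. The wall impedance is a
#' *specific* impedance (Pa s/m): `"rigid"` walls are lossless, `"default"`
#' uses 500 * rho * c (an empirical value giving appropriate damping for
#' plaster-coated printed resonators), and any finite number (possibly
#' complex, real part >= 0) can be supplied per section.
#'
#' @param length_m Section length in m, >= 0.
#' @param area_m2 Cross-sectional area in m^2, > 0.
#' @param wall_impedance `"rigid"`, `"default"`, or a specific impedance in
#'   Pa s/m.
#' @return A list of class `tube_section`.
#' @export
tube_section <- function(length_m, area_m2, wall_impedance = "default") {
  stopifnot(is.numeric(length_m), length(length_m) == 1L, length_m >= 0,
            is.numeric(area_m2), length(area_m2) == 1L, area_m2 > 0)
  if (is.character(wall_impedance)) {
    wall_impedance <- match.arg(wall_impedance, c("default", "rigid"))
  } else {
    wall_impedance <- as.complex(wall_impedance)
    if (Re(wall_impedance) < 0) stop("wall impedance must have Re >= 0")
  }
  structure(list(length_m = as.numeric(length_m),
                 area_m2 = as.numeric(area_m2),
                 wall_impedance = wall_impedance),
            class = "tube_section")
}

#' Default wall impedance: 500 * rho * c (specific, Pa s/m)
#' @param constants An [acoustic_constants()] object.
#' @return A real scalar, 205800 Pa s/m for the default constants.
#' @export
default_wall_impedance <- function(constants = acoustic_constants()) {
  500 * constants$density * constants$speed_of_sound
}

resolve_wall_impedance <- function(section, constants) {
  w <- section$wall_impedance
  if (identical(w, "rigid")) return(NULL)
  if (identical(w, "default")) return(as.complex(default_wall_impedance(constants)))
  w
}

#' Transmission matrix of a uniform tube section
#'
#' Plane-wave chain matrix of a cylindrical duct of length `L` and area `A`,
#' with optional distributed wall loss. Per unit length the series impedance
#' is `Z' = j omega rho / A` and the shunt admittance `Y' = j omega A /
#' (rho c^2) + l_perim / Zwall`, where `l_perim = 2 sqrt(pi A)` is the
#' perimeter of the area-equivalent circle and `Zwall` the specific wall
#' impedance (the wall term is dropped for rigid walls). With the
#' propagation constant `Gamma = sqrt(Z' Y')` and section characteristic
#' impedance `Zc = sqrt(Z'/Y')` the matrix is
#'
#' \deqn{\begin{pmatrix}\cosh\Gamma L & Z_c \sinh\Gamma L\\
#'       \sinh(\Gamma L)/Z_c & \cosh\Gamma L\end{pmatrix}}
#'
#' which is reciprocal (det = 1) for any wall impedance. For rigid walls it
#' reduces to the lossless form `[[cos kL, j Z0 sin kL], [j sin(kL)/Z0,
#' cos kL]]` with `Z0 = rho c / A`.
#'
#' @param section A [tube_section()].
#' @param frequencies_hz Frequency grid (Hz), all > 0.
#' @param constants An [acoustic_constants()] object.
#' @return A `tm_series` labeled `"vocal_tract"`.
#' @export
uniform_tube_matrix <- function(section, frequencies_hz,
                                constants = acoustic_constants()) {
  f <- freq_grid(frequencies_hz)
  if (section$area_m2 <= 0) stop("tube section must have positive area")
  w <- omega(f)
  rho <- constants$density
  c0 <- constants$speed_of_sound
  A <- section$area_m2
  L <- section$length_m
  if (L == 0) return(tm_identity(f))

  zp <- complex(imaginary = w * rho / A)           # series impedance / length
  yp <- complex(imaginary = w * A / (rho * c0^2))  # shunt admittance / length
  zw <- resolve_wall_impedance(section, constants)
  if (!is.null(zw)) {
    l_perim <- 2 * sqrt(pi * A)
    yp <- yp + l_perim / zw
  }
  gam <- sqrt(zp * yp)
  zc <- sqrt(zp / yp)
  gl <- gam * L
  ch <- cosh(gl); sh <- sinh(gl)
  tm_series(f, m11 = ch, m12 = zc * sh, m21 = sh / zc, m22 = ch,
            label = "vocal_tract")
}

#' Input impedance of a closed side-branch tube
#'
#' Acoustic input impedance of a hard-terminated branch tube of length `Lb`
#' and area `Ab`: `Zb = Zc coth(Gamma Lb)`, which for rigid walls reduces to
#' `-j Z0 cot(k Lb)`. Its zeros (branch quarter-wave frequencies, odd
#' multiples of `c / (4 Lb)`) produce spectral zeros in the main-tract
#' transfer function, the pole-zero-pair phenomenology of side cavities such
#' as the piriform sinuses.
#'
#' @param section A [tube_section()] describing the branch.
#' @inheritParams uniform_tube_matrix
#' @return An [impedance_spectrum()] with `convention = "acoustic"`.
#' @export
closed_branch_impedance <- function(section, frequencies_hz,
                                    constants = acoustic_constants()) {
  f <- freq_grid(frequencies_hz)
  m <- uniform_tube_matrix(section, f, constants)
  # closed far end: U_out = 0 -> Zin = m11 / m21
  impedance_spectrum(f, m$m11 / m$m21, convention = "acoustic")
}

#' Shunt two-port of a side branch
#'
#' A side cavity attached to the main tract acts as a shunt admittance at
#' its attachment point: `[[1, 0], [1/Zb, 1]]`, with `Zb` the branch input
#' impedance (acoustic convention). Always reciprocal (det = 1).
#'
#' @param branch_input_impedance An [impedance_spectrum()] (acoustic) of the
#'   branch, nonzero at all grid points. A branch zero falling exactly on a
#'   grid point makes the shunt admittance infinite there; shift the grid.
#' @return A `tm_series` labeled `"side_branch"`.
#' @export
side_branch_matrix <- function(branch_input_impedance) {
  zb <- branch_input_impedance
  if (imp_convention(zb) != "acoustic") {
    stop("branch input impedance must be in the acoustic convention")
  }
  bad <- which(zb$z == 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "branch input impedance is exactly zero at %d grid point(s) (first at %g Hz); shift the grid",
      length(bad), zb$frequency_hz[bad[1]]))
  }
  tm_series(zb$frequency_hz, m11 = 1 + 0i, m12 = 0i, m21 = 1 / zb$z,
            m22 = 1 + 0i, label = "side_branch")
}

#' Area function of a tube-like resonator
#'
#' An ordered sequence of [tube_section()]s from the glottis (first) to the
#' lips (last), with optional closed-tube side branches attached at the
#' lips-side end of named sections.
#'
#' @param sections A list of [tube_section()]s, glottis to lips.
#' @param branches Optional named list; each element
#'   `list(after_section = i, section = tube_section(...))` attaches a
#'   closed branch at the downstream end of section `i`.
#' @return A list of class `area_function` with elements `sections` and
#'   `branches`, plus `area_glottis_m2`, `area_lips_m2`, `total_length_m`.
#' @export
area_function <- function(sections, branches = list()) {
  if (inherits(sections, "tube_section")) sections <- list(sections)
  stopifnot(length(sections) > 0,
            all(vapply(sections, inherits, logical(1), "tube_section")))
  total <- sum(vapply(sections, `[[`, numeric(1), "length_m"))
  if (total <= 0) stop("area function must have positive total length")
  for (b in branches) {
    stopifnot(is.list(b), inherits(b$section, "tube_section"),
              b$after_section >= 1, b$after_section <= length(sections))
  }
  structure(list(
    sections = sections,
    branches = branches,
    area_glottis_m2 = sections[[1]]$area_m2,
    area_lips_m2 = sections[[length(sections)]]$area_m2,
    total_length_m = total
  ), class = "area_function")
}

#' Chain matrix of a full area function
#'
#' Cascades the section matrices glottis -> lips, interleaving side-branch
#' shunts at their attachment points. Splitting any section in two leaves
#' the result unchanged (semigroup property of the chain matrices).
#'
#' @param af An [area_function()].
#' @inheritParams uniform_tube_matrix
#' @return A `tm_series` labeled `"vocal_tract"`.
#' @export
area_function_matrix <- function(af, frequencies_hz,
                                 constants = acoustic_constants()) {
  f <- freq_grid(frequencies_hz)
  m <- NULL
  for (i in seq_along(af$sections)) {
    mi <- uniform_tube_matrix(af$sections[[i]], f, constants)
    m <- if (is.null(m)) mi else cascade(m, mi, label = "vocal_tract")
    for (b in af$branches) {
      if (b$after_section == i) {
        zb <- closed_branch_impedance(b$section, f, constants)
        m <- cascade(m, side_branch_matrix(zb), label = "vocal_tract")
      }
    }
  }
  attr(m, "label") <- "vocal_tract"
  m
}

#' Canonical uniform-tube resonator (the schwa-like tube)
#'
#' A straight hard-printed tube of 170 mm length and 27.6 mm inner diameter,
#' the simplest physical vocal-tract stand-in (close to a neutral schwa
#' configuration). Its lips aperture is `pi * 0.0138^2 ~ 5.98 cm^2`.
#'
#' @param wall_impedance Passed to [tube_section()]; the default is the
#'   empirical 500 * rho * c.
#' @return An [area_function()] with one section.
#' @export
schwa_tube <- function(wall_impedance = "default") {
  area_function(tube_section(0.170, pi * 0.0138^2, wall_impedance))
}

#' Demonstration resonator with a piriform-like side branch
#'
#' The uniform 170 mm tube with a single closed 20 mm side branch attached
#' 30 mm above the glottis. The branch quarter-wave frequency `c / (4 *
#' 0.02) ~ 4.3 kHz` puts a strong spectral zero between 4 and 5 kHz, the
#' signature that piriform sinus cavities leave in vowel transfer functions.
#'
#' @inheritParams schwa_tube
#' @param branch_length_m Branch length in m (default 0.02).
#' @param branch_area_m2 Branch area in m^2 (default 0.5 cm^2).
#' @return An [area_function()].
#' @export
piriform_demo <- function(wall_impedance = "default",
                          branch_length_m = 0.02,
                          branch_area_m2 = 0.5e-4) {
  main_area <- pi * 0.0138^2
  area_function(
    sections = list(
      tube_section(0.030, main_area, wall_impedance),
      tube_section(0.140, main_area, wall_impedance)
    ),
    branches = list(piriform = list(
      after_section = 1,
      section = tube_section(branch_length_m, branch_area_m2, wall_impedance)
    ))
  )
}

#' Read / write an area function as CSV
#'
#' Columns: `section_index` (0-based, glottis -> lips), `length_m`,
#' `area_m2`, `wall_impedance_specific` (blank = default 500 rho c;
#' `"rigid"` for lossless), and optionally `branch_id`, `branch_length_m`,
#' `branch_area_m2` for a closed branch attached at the lips-side end of
#' that section.
#'
#' @param af An [area_function()].
#' @param path File path.
#' @return `path` invisibly (write); an `area_function` (read).
#' @export
write_area_function <- function(af, path) {
  n <- length(af$sections)
  wall_chr <- vapply(af$sections, function(s) {
    if (identical(s$wall_impedance, "default")) "" else
      if (identical(s$wall_impedance, "rigid")) "rigid" else
        as.character(Re(s$wall_impedance))
  }, character(1))
  d <- tibble::tibble(
    section_index = seq_len(n) - 1L,
    length_m = vapply(af$sections, `[[`, numeric(1), "length_m"),
    area_m2 = vapply(af$sections, `[[`, numeric(1), "area_m2"),
    wall_impedance_specific = wall_chr,
    branch_id = NA_character_,
    branch_length_m = NA_real_,
    branch_area_m2 = NA_real_
  )
  nm <- names(af$branches)
  for (j in seq_along(af$branches)) {
    b <- af$branches[[j]]
    i <- b$after_section
    d$branch_id[i] <- if (!is.null(nm) && nzchar(nm[j])) nm[j] else paste0("branch", j)
    d$branch_length_m[i] <- b$section$length_m
    d$branch_area_m2[i] <- b$section$area_m2
  }
  readr::write_csv(d, path, na = "")
  invisible(path)
}

#' @rdname write_area_function
#' @export
read_area_function <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                       col_types = readr::cols(
                         wall_impedance_specific = readr::col_character(),
                         branch_id = readr::col_character(),
                         .default = readr::col_guess()))
  d <- d[order(d$section_index), ]
  parse_wall <- function(x) {
    if (is.na(x) || !nzchar(x)) "default"
    else if (identical(x, "rigid")) "rigid"
    else as.numeric(x)
  }
  sections <- purrr::pmap(
    list(d$length_m, d$area_m2, d$wall_impedance_specific),
    function(l, a, w) tube_section(l, a, parse_wall(w)))
  branches <- list()
  if ("branch_id" %in% names(d)) {
    for (i in seq_len(nrow(d))) {
      if (!is.na(d$branch_id[i]) && nzchar(d$branch_id[i])) {
        branches[[d$branch_id[i]]] <- list(
          after_section = i,
          section = tube_section(d$branch_length_m[i], d$branch_area_m2[i],
                                 parse_wall(d$wall_impedance_specific[i])))
      }
    }
  }
  area_function(sections, branches)
}
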