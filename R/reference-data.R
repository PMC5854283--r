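#' Benchmark formant data for four printed vocal-tract resonators
#'
#' Published benchmark measurements for four 3D-printed vocal-tract
#' resonators — the vowels /a/, /u/ and /i/ of a male speaker and the
#' uniform schwa-like tube — characterized three ways: the FEM reference
#' simulation (`fem`), the blocked-pressure ratio measurement `P1/P3`
#' (`p1_p3`), and the free-field-normalized measurement `P1/Pref`
#' (`p1_pref`). For each model and method the first four formants are given
#' with frequency (Hz), -3 dB bandwidth (Hz) and amplitude (dB).
#'
#' These are the standard comparison inputs for the package's aggregate
#' statistics: e.g. the mean absolute formant-frequency deviation of the
#' blocked-ratio measurement from the FEM reference over all 16 formants.
#'
#' @param model One of `"a"`, `"u"`, `"i"`, `"schwa"`, or `"all"`.
#' @param method One of `"fem"`, `"p1_p3"`, `"p1_pref"`, or `"all"`.
#' @return A tibble with columns `model`, `method`, `formant`,
#'   `frequency_hz`, `bandwidth_hz`, `amplitude_db`. With a single model
#'   and method it is also a valid [formant_table()] input for
#'   [compare_formant_tables()].
#' @examples
#' ref <- benchmark_formants("schwa", "fem")
#' meas <- benchmark_formants("schwa", "p1_p3")
#' glance(compare_formant_tables(meas, ref))
#' @export
benchmark_formants <- function(model = "all", method = "all") {
  d <- benchmark_formant_data()
  if (!identical(model, "all")) {
    stopifnot(all(model %in% unique(d$model)))
    d <- d[d$model %in% model, ]
  }
  if (!identical(method, "all")) {
    stopifnot(all(method %in% unique(d$method)))
    d <- d[d$method %in% method, ]
  }
  d
}

benchmark_formant_data <- function() {
  models <- rep(c("a", "u", "i", "schwa"), each = 4)
  formants <- rep(1:4, times = 4)
  grid_row <- function(method, freq, bw, amp) {
    tibble::tibble(model = models, method = method, formant = formants,
                   frequency_hz = freq, bandwidth_hz = bw, amplitude_db = amp)
  }
  dplyr::bind_rows(
    grid_row(
      "fem",
      c(557, 971, 2680, 3077, 288, 737, 2481, 2846,
        241, 1841, 2646, 3233, 472, 1420, 2379, 3348),
      c(43.3, 44.9, 86.1, 72.6, 30.1, 30.0, 40.2, 39.2,
        25.4, 41.9, 97.5, 93.7, 21.12, 52.2, 104.0, 166.1),
      c(27.0, 25.0, 18.5, 21.3, 21.5, 16.1, 11.4, 13.6,
        20.0, 16.2, 17.4, 22.9, 29.0, 21.0, 14.7, 10.4)
    ),
    grid_row(
      "p1_p3",
      c(557, 975, 2676, 3020, 289, 740, 2510, 2869,
        235, 1812, 2606, 3121, 476, 1434, 2402, 3354),
      c(18.4, 30.6, 69.9, 92.3, 48.6, 80.5, 80.0, 84.4,
        14.2, 29.9, 78.8, 140.3, 10.1, 33.1, 79.4, 133.7),
      c(35.4, 29.1, 21.1, 20.2, 18.5, 9.8, 7.7, 9.3,
        25.5, 19.4, 20.4, 18.5, 36.4, 25.6, 17.1, 11.7)
    ),
    grid_row(
      "p1_pref",
      c(558, 975, 2675, 3024, 289, 741, 2513, 2869,
        235, 1812, 2604, 3106, 476, 1434, 2400, 3358),
      c(18.6, 30.7, 67.9, 88.5, 47.8, 87.9, 85.5, 84.1,
        14.2, 29.6, 78.3, 163.5, 10.1, 32.9, 79.5, 135.0),
      c(36.7, 31.7, 27.9, 27.4, 19.3, 11.4, 11.7, 12.9,
        25.7, 22.1, 24.4, 23.5, 37.8, 27.9, 20.1, 16.7)
    )
  )
}

#' Aggregate deviation statistics over the benchmark models
#'
#' Pools the per-formant deviations of a measurement method from the FEM
#' reference across all four benchmark resonators (16 formants) and
#' returns the mean absolute relative frequency deviation (%), mean
#' absolute bandwidth deviation (Hz) and mean absolute amplitude deviation
#' (dB).
#'
#' @param method `"p1_p3"` or `"p1_pref"`.
#' @return A one-row tibble as from [glance.formant_comparison()].
#' @export
benchmark_aggregate_deviation <- function(method = c("p1_p3", "p1_pref")) {
  method <- match.arg(method)
  d <- benchmark_formant_data()
  ref <- d[d$method == "fem", ]
  meas <- d[d$method == method, ]
  # align by model and formant
  key <- function(x) paste(x$model, x$formant)
  meas <- meas[match(key(ref), key(meas)), ]
  glance(compare_formant_tables(meas, ref))
}
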