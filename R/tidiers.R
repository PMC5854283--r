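#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transfer function into magnitude / phase rows
#'
#' @param x A [transfer_function()].
#' @param ... Unused.
#' @return A tibble with columns `frequency_hz`, `mag_db`, `phase_rad`,
#'   `provenance`.
#' @export
tidy.transfer_function <- function(x, ...) {
  tibble::tibble(frequency_hz = x$frequency_hz,
                 mag_db = tf_mag_db(x),
                 phase_rad = Arg(x$h),
                 provenance = x$provenance)
}

#' One-row summary of a transfer function
#'
#' @param x A [transfer_function()].
#' @param ... Passed to [find_formants()].
#' @return A tibble with the band, point count, low-frequency level and
#'   first-formant summary.
#' @export
glance.transfer_function <- function(x, ...) {
  ft <- find_formants(x, ...)
  tibble::tibble(
    n_freq = nrow(x),
    f_min_hz = min(x$frequency_hz),
    f_max_hz = max(x$frequency_hz),
    low_freq_level_db = tf_mag_db(x)[1],
    n_formants = nrow(ft),
    f1_hz = if (nrow(ft) > 0) ft$frequency_hz[1] else NA_real_,
    provenance = unique(x$provenance)
  )
}

#' Tidy a formant table
#' @param x A [formant_table()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.formant_table <- function(x, ...) tibble::as_tibble(x)

#' Plot a transfer-function magnitude spectrum
#'
#' @param object A [transfer_function()].
#' @param ... Additional transfer functions to overlay (named arguments
#'   become legend labels).
#' @return A ggplot.
#' @export
autoplot.transfer_function <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "transfer_function")]
  dfs <- c(list(object), extra)
  labels <- c(unique(object$provenance),
              if (length(extra)) names(extra) else NULL)
  if (length(labels) != length(dfs) || any(!nzchar(labels))) {
    labels <- vapply(dfs, function(d) unique(d$provenance), character(1))
  }
  d <- purrr::map2_dfr(dfs, make.unique(labels), function(tf, lab) {
    tibble::tibble(frequency_hz = tf$frequency_hz, mag_db = tf_mag_db(tf),
                   model = lab)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency_hz, y = .data$mag_db,
                                  colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "|H| (dB)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a formant table over a transfer function
#'
#' @param h A [transfer_function()].
#' @param ft A [formant_table()] (default: extracted from `h`).
#' @return A ggplot with formant markers and -3 dB bandwidth bars.
#' @export
plot_formants <- function(h, ft = find_formants(h)) {
  base <- autoplot.transfer_function(h)
  fd <- tibble::as_tibble(ft)
  base +
    ggplot2::geom_vline(data = fd,
                        ggplot2::aes(xintercept = .data$frequency_hz),
                        linetype = "dotted") +
    ggplot2::geom_segment(
      data = dplyr::filter(fd, !is.na(.data$bandwidth_hz)),
      ggplot2::aes(x = .data$frequency_hz - .data$bandwidth_hz / 2,
                   xend = .data$frequency_hz + .data$bandwidth_hz / 2,
                   y = .data$amplitude_db - 3,
                   yend = .data$amplitude_db - 3),
      inherit.aes = FALSE, colour = "grey40")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
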