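#' Run configuration
#'
#' Flat key-value configuration for a full pipeline run, parsed from an
#' INI-like text file (`key = value`, `#` comments). Recognized keys:
#' `resonator` (area-function CSV path, or `schwa_tube` / `piriform_demo`),
#' `mesh` (MSH path or `cylinder:<radius>:<length>:<edge>`), `grid_step`,
#' `grid_max`, `zwall` (specific, or `rigid`), `environment`
#' (`monopole`/`random`), `seed`, `distance`, `speed_of_sound`, `density`,
#' `out_dir`, `log_level`.
#'
#' @param path Path to a config file, or `NULL` to start from defaults.
#' @param ... Named overrides applied on top.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    resonator = "schwa_tube", mesh = NULL,
    grid_step = 3, grid_max = 6000,
    zwall = "default", environment = "monopole", seed = 1L,
    distance = 0.25, speed_of_sound = 343.0, density = 1.20,
    out_dir = ".", log_level = "INFO"
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path)
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  # hash the scientific configuration only: output locations and logging
  # do not affect results, so runs into different directories with the
  # same physics produce identical artifacts and identical hashes
  cfg <- cfg[setdiff(sort(names(cfg)), c("out_dir", "log_level"))]
  txt <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                  character(1)),
               sep = "=", collapse = ";")
  # small stable polynomial hash; enough to tie artifacts to their config
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_msg <- function(cfg, level, stage, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[[level]] >= levels[[cfg$log_level %||% "INFO"]]) {
    message(sprintf("[%s] %s %s: %s", format(Sys.time(), "%H:%M:%S"),
                    level, stage, paste0(...)))
  }
}

provenance_header <- function(cfg) {
  c(sprintf("# tracttf %s", as.character(utils::packageVersion("tracttf"))),
    sprintf("# config_hash %s", config_hash(cfg)),
    sprintf("# seed %s", cfg$seed),
    sprintf("# constants c=%g rho=%g", cfg$speed_of_sound, cfg$density))
}

write_csv_with_header <- function(df, path, cfg) {
  writeLines(provenance_header(cfg), path)
  suppressWarnings(readr::write_csv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Generate canonical fixture files
#'
#' Writes ready-to-use input files for the bundled demonstration
#' resonators:
#' * `schwa_tube`: area-function CSV of the 170 mm x 27.6 mm uniform tube
#'   plus a cylinder mesh spec file,
#' * `piriform_demo`: the same tube with a closed 20 mm side branch whose
#'   quarter-wave zero falls between 4 and 5 kHz,
#' * `resonator2nd`: analytic frequency-response CSV of a single
#'   second-order resonance (f0 = 500 Hz, Q = 20), handy as a known
#'   oracle for analysis tools.
#'
#' @param name One of `"schwa_tube"`, `"piriform_demo"`, `"resonator2nd"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture <- function(name = c("schwa_tube", "piriform_demo",
                                  "resonator2nd"), dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if (name == "schwa_tube") {
    p <- file.path(dir, "schwa_tube_area.csv")
    write_area_function(schwa_tube(), p)
    files <- c(files, p)
    p2 <- file.path(dir, "schwa_tube_cylinder.txt")
    writeLines(c("# cylinder mesh spec: radius_m length_m target_edge_m",
                 "0.0138 0.170 0.003"), p2)
    files <- c(files, p2)
  } else if (name == "piriform_demo") {
    p <- file.path(dir, "piriform_demo_area.csv")
    write_area_function(piriform_demo(), p)
    files <- c(files, p)
  } else {
    f <- seq(3, 6000, by = 3)
    f0 <- 500; q <- 20
    h <- 1 / (1 - (f / f0)^2 + 1i * f / (f0 * q))
    p <- file.path(dir, "resonator2nd_frf.csv")
    readr::write_csv(tibble::tibble(frequency_hz = f, re_h = Re(h),
                                    im_h = Im(h),
                                    mag_db = 20 * log10(Mod(h))), p)
    files <- c(files, p)
  }
  invisible(files)
}

#' Write / read a transfer function as CSV
#'
#' Columns: `frequency_hz, re_h, im_h, mag_db`. Provenance comment lines
#' beginning with `#` are skipped on read.
#'
#' @param tf A [transfer_function()].
#' @param path File path.
#' @param provenance Provenance tag to use on read.
#' @return `path` invisibly (write); a `transfer_function` (read).
#' @export
write_transfer_csv <- function(tf, path) {
  readr::write_csv(tibble::tibble(frequency_hz = tf$frequency_hz,
                                  re_h = Re(tf$h), im_h = Im(tf$h),
                                  mag_db = tf_mag_db(tf)), path)
  invisible(path)
}

#' @rdname write_transfer_csv
#' @export
read_transfer_csv <- function(path, provenance = "chain_matrix") {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  transfer_function(d$frequency_hz,
                    complex(real = d$re_h, imaginary = d$im_h),
                    provenance = provenance)
}

resolve_resonator <- function(cfg) {
  r <- cfg$resonator
  if (identical(r, "schwa_tube")) return(schwa_tube())
  if (identical(r, "piriform_demo")) return(piriform_demo())
  read_area_function(r)
}

#' Run the full simulation pipeline from a configuration
#'
#' Chains chain-matrix simulation, (optionally) the FEM reference solve,
#' formant analysis and the chain-vs-FEM comparison as configured, writing
#' every artifact with a provenance header (package version, config hash,
#' seed, constants).
#'
#' @param cfg A [run_config()].
#' @param fem Logical: also run the FEM reference (cylinder resonators
#'   only; uses coarse-scan formant refinement). Default `FALSE`.
#' @return A list with `transfer` (chain-matrix [transfer_function()]),
#'   `formants` (a [formant_table()]), and when `fem = TRUE` also
#'   `fem_formants` and `comparison`; plus `files`, the artifacts written.
#' @export
run_pipeline <- function(cfg = run_config(), fem = FALSE) {
  constants <- acoustic_constants(cfg$speed_of_sound, cfg$density)
  af <- resolve_resonator(cfg)
  grid <- freq_grid(seq(cfg$grid_step, cfg$grid_max, by = cfg$grid_step))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  files <- character(0)

  log_msg(cfg, "INFO", "simulate-tf", "chain-matrix transfer function")
  h <- chain_transfer_function(af, grid, constants)
  p <- file.path(cfg$out_dir, "transfer_chain.csv")
  write_csv_with_header(tibble::tibble(frequency_hz = h$frequency_hz,
                                       re_h = Re(h$h), im_h = Im(h$h),
                                       mag_db = tf_mag_db(h)), p, cfg)
  files <- c(files, p)

  log_msg(cfg, "INFO", "analyze", "formant extraction")
  ft <- find_formants(h)
  p <- file.path(cfg$out_dir, "formants_chain.csv")
  write_csv_with_header(ft, p, cfg)
  files <- c(files, p)

  out <- list(transfer = h, formants = ft)
  if (isTRUE(fem)) {
    log_msg(cfg, "INFO", "fem-tf", "FEM reference solve")
    if (length(af$sections) != 1L) {
      stop("fem stage: built-in meshing supports single-section cylinders only")
    }
    sec <- af$sections[[1]]
    mesh <- cylinder_mesh(effective_radius(sec$area_m2), sec$length_m)
    zwall <- if (identical(cfg$zwall, "rigid")) Inf
    else if (identical(cfg$zwall, "default")) default_wall_impedance(constants)
    else cfg$zwall
    hfun <- fem_solver_function(mesh, constants, zwall = zwall)
    fem_ft <- formants_from_solver(hfun, f_max = cfg$grid_max)
    p <- file.path(cfg$out_dir, "formants_fem.csv")
    write_csv_with_header(fem_ft, p, cfg)
    files <- c(files, p)

    log_msg(cfg, "INFO", "compare", "chain vs FEM formants")
    ncmp <- min(nrow(ft), nrow(fem_ft))
    cmp <- compare_formant_tables(ft[seq_len(ncmp), ], fem_ft[seq_len(ncmp), ])
    p <- file.path(cfg$out_dir, "comparison_chain_vs_fem.csv")
    write_csv_with_header(cmp, p, cfg)
    files <- c(files, p)
    out$fem_formants <- fem_ft
    out$comparison <- cmp
  }
  out$files <- files
  out$config_hash <- config_hash(cfg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
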