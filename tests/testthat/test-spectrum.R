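test_that("a single second-order resonance yields F = f0 and BW = f0/Q", {
  g <- default_grid(step = 3)
  h <- resonator_tf(g, f0 = 500, q = 20)
  ft <- find_formants(h)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$frequency_hz, 500, tolerance = 0.5 / 500)
  expect_equal(ft$bandwidth_hz, 25, tolerance = 0.5 / 25)
  expect_equal(ft$amplitude_db, 20 * log10(20), tolerance = 0.05)
})

test_that("flat spectra produce an empty formant table", {
  g <- coarse_grid()
  h <- transfer_function(g, rep(1 + 0i, length(g)))
  ft <- find_formants(h)
  expect_equal(nrow(ft), 0L)
})

test_that("the uniform-tube model yields four formants near the benchmark values", {
  h <- chain_transfer_function(schwa_tube(), default_grid())
  ft <- find_formants(h)
  ref <- benchmark_formants("schwa", "fem")
  expect_equal(nrow(ft), 4L)
  expect_lt(max(abs(ft$frequency_hz / ref$frequency_hz - 1)), 0.01)
})

test_that("refining the grid tenfold moves formants by less than 0.1 percent", {
  # a peak resolved by several grid steps: Q = 5 resonance on 30 vs 3 Hz
  f_coarse <- find_formants(resonator_tf(default_grid(step = 30), q = 5))
  f_fine <- find_formants(resonator_tf(default_grid(step = 3), q = 5))
  expect_lt(abs(f_coarse$frequency_hz / f_fine$frequency_hz - 1), 1e-3)
  # the uniform tube on its standard grid vs a 10x finer one
  h3 <- chain_transfer_function(schwa_tube(), default_grid(step = 3))
  h03 <- chain_transfer_function(schwa_tube(), default_grid(step = 0.3))
  ft3 <- find_formants(h3)$frequency_hz
  ft03 <- find_formants(h03)$frequency_hz
  expect_equal(length(ft3), length(ft03))
  expect_lt(max(abs(ft3 / ft03 - 1)), 1e-3)
})

test_that("RMS spectral difference behaves on constants, offsets and ripple", {
  g <- default_grid(step = 3)
  h <- resonator_tf(g)
  expect_equal(rms_spectral_difference(h, h), 0)
  h6 <- transfer_function(g, h$h * 10^(6 / 20))
  expect_equal(rms_spectral_difference(h6, h), 6, tolerance = 1e-10)
  ripple_db <- 2 * sin(2 * pi * as.numeric(g) / 500)
  hr <- transfer_function(g, h$h * 10^(ripple_db / 20))
  expect_equal(rms_spectral_difference(hr, h), 2 / sqrt(2), tolerance = 0.01)
  h_short <- transfer_function(freq_grid(seq(7000, 8000, 10)), rep(1 + 0i, 101))
  expect_error(rms_spectral_difference(h, h_short), "overlap")
})

test_that("formant-table comparison reproduces per-entry and pooled deviations", {
  ref <- benchmark_formants("schwa", "fem")
  meas <- benchmark_formants("schwa", "p1_p3")
  cmp <- compare_formant_tables(meas, ref)
  expect_equal(cmp$freq_dev_pct[1], 0.85, tolerance = 0.005)
  same <- compare_formant_tables(ref, ref)
  expect_equal(same$freq_dev_pct, rep(0, 4))
  expect_equal(same$bw_dev_hz, rep(0, 4))
  expect_error(compare_formant_tables(meas[1:3, ], ref), "mismatch")
})

test_that("merged -3 dB flanks fall back to symmetric reflection with a flag", {
  # two closely spaced peaks whose shared valley stays above -3 dB of each
  g <- freq_grid(seq(100, 1200, by = 1))
  f <- as.numeric(g)
  y_db <- 20 * exp(-((f - 600) / 60)^2) + 20 * exp(-((f - 700) / 60)^2)
  h <- transfer_function(g, 10^(y_db / 20) + 0i)
  ft <- find_formants(h, max_n = 2, min_prominence_db = 1)
  expect_equal(nrow(ft), 2L)
  expect_true(any(grepl("bw_reflected", ft$flag)))
  expect_true(all(is.finite(ft$bandwidth_hz)))
})

test_that("tidy and glance methods summarize transfer functions and comparisons", {
  h <- chain_transfer_function(schwa_tube(), default_grid(step = 10))
  td <- tidy(h)
  expect_named(td, c("frequency_hz", "mag_db", "phase_rad", "provenance"))
  gl <- glance(h)
  expect_equal(gl$n_formants, 4L)
  expect_equal(gl$f1_hz, 472, tolerance = 0.01)
  agg <- glance(compare_formant_tables(benchmark_formants("schwa", "p1_p3"),
                                       benchmark_formants("schwa", "fem")))
  expect_named(agg, c("n_formants", "mean_abs_freq_dev_pct",
                      "mean_abs_bw_dev_hz", "mean_abs_amp_dev_db"))
})

test_that("autoplot and formant overlays build valid ggplot objects", {
  h <- chain_transfer_function(schwa_tube(), default_grid(step = 30))
  p1 <- ggplot2::autoplot(h)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_formants(h)
  expect_s3_class(p2, "ggplot")
})
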