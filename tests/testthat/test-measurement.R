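test_that("open-circuit pressure of a pure shunt is -Us/Y", {
  g <- freq_grid(c(100, 500, 1000))
  y <- c(2 + 1i, -3 + 0.5i, 0.1 - 4i)
  net <- tm_series(g, 1 + 0i, 0i, y, 1 + 0i)
  p <- open_circuit_pressure(net, us = 2 + 0i)
  expect_equal(p, -2 / y, tolerance = 1e-12)
})

test_that("a network with no coupling path is rejected", {
  g <- freq_grid(c(100, 200))
  expect_error(open_circuit_pressure(tm_identity(g)), "no coupling path")
})

test_that("det-1 simplification holds on random reciprocal matrices", {
  g <- coarse_grid()
  for (seed in 1:10) {
    m <- random_reciprocal_tm(g, seed)
    general <- (m$m12 - m$m11 * m$m22 / m$m21)
    det1 <- -1 / m$m21
    expect_rel_equal(general, det1, 1e-10)
  }
})

test_that("environment two-ports satisfy their input-impedance and det constraints", {
  g <- coarse_grid()
  zr <- as_acoustic(piston_in_baffle(g, 0.0138), schwa_area)
  n_rand <- environment_reciprocal(zr, mode = "random", seed = 5)
  expect_rel_equal(n_rand$m11 / n_rand$m21, zr$z, 1e-12)
  expect_lt(attr(reciprocity_deviation(n_rand), "max_deviation"), 1e-12)
  # the monopole entries span many orders of magnitude, so the determinant
  # cancellation meets the physical-element bound rather than machine eps
  n_mono <- environment_reciprocal(zr, mode = "monopole")
  expect_rel_equal(n_mono$m11 / n_mono$m21, zr$z, 1e-12)
  expect_lt(attr(reciprocity_deviation(n_mono), "max_deviation"), 1e-9)
})

test_that("the blocked-pressure ratio equals the direct transfer function for any environment", {
  g <- default_grid(step = 10)
  af <- schwa_tube()
  m <- area_function_matrix(af, g)
  zr <- as_acoustic(piston_in_baffle(g, effective_radius(af$area_lips_m2)),
                    af$area_lips_m2)
  hd <- transfer_direct(m, zr)
  hs <- list()
  for (seed in 1:25) {
    n <- environment_reciprocal(zr, mode = "random", seed = seed)
    hb <- blocked_ratio_transfer(m, n)
    expect_rel_equal(hb$h, hd$h, 1e-10)
    hs[[seed]] <- n$m12
  }
  # different seeds genuinely produce different environments
  expect_gt(max(Mod(hs[[1]] - hs[[2]])), 1e-3)
  # secondary identity: P1/P3 = n21/o21 when both dets are 1
  n <- environment_reciprocal(zr, mode = "random", seed = 99)
  o <- cascade(m, n)
  expect_rel_equal(blocked_ratio_transfer(m, n)$h, n$m21 / o$m21, 1e-10)
})

test_that("the blocked-pressure ratio is exactly independent of the source spectrum", {
  g <- coarse_grid()
  af <- schwa_tube()
  m <- area_function_matrix(af, g)
  zr <- as_acoustic(piston_in_baffle(g, effective_radius(af$area_lips_m2)),
                    af$area_lips_m2)
  n <- environment_reciprocal(zr, mode = "random", seed = 3)
  h1 <- blocked_ratio_transfer(m, n, us = 1 + 0i)
  withr::local_seed(21)
  us2 <- complex(real = stats::runif(length(g), 0.5, 3),
                 imaginary = stats::runif(length(g), -1, 1))
  h2 <- blocked_ratio_transfer(m, n, us = us2)
  expect_identical(h1$h, h2$h)
})

test_that("direct transfer of a rigid tube with zero load is 1/cos(kL)", {
  g <- freq_grid(seq(100, 400, by = 10))  # well below the first pole
  m <- area_function_matrix(schwa_tube("rigid"), g)
  zr0 <- impedance_spectrum(g, 0i, convention = "acoustic")
  h <- transfer_direct(m, zr0)
  expect_rel_equal(Mod(h$h), 1 / abs(cos(2 * pi * g * 0.170 / 343)), 1e-10)
  # identity tract: H = 1 for any load
  hid <- transfer_direct(tm_identity(g),
                         as_acoustic(piston_in_baffle(g, 0.0138), schwa_area))
  expect_equal(hid$h, rep(1 + 0i, length(g)))
})

test_that("the transfer function approaches 0 dB at the lowest grid frequency", {
  g <- freq_grid(c(3, seq(50, 6000, by = 50)))
  h <- chain_transfer_function(schwa_tube(), g)
  expect_equal(Mod(h$h[1]), 1, tolerance = 1e-3)
})

test_that("the single-measurement prediction tilts upward with the radiation load", {
  g <- default_grid(step = 30)
  af <- schwa_tube()
  h <- chain_transfer_function(af, g)
  zr <- as_acoustic(piston_in_baffle(g, effective_radius(af$area_lips_m2)),
                    af$area_lips_m2)
  z0 <- characteristic_impedance(af$area_lips_m2, frequencies_hz = g)
  kp <- kitamura_prediction(h, zr, z0)
  # with Zr = 0 the prediction collapses to Ps H
  zr0 <- impedance_spectrum(g, 0i, convention = "acoustic")
  kp0 <- kitamura_prediction(h, zr0, z0, ps = 3 + 0i)
  expect_equal(kp0$p1, 3 * h$h)
  expect_equal(kp0$tilt_db, rep(0, length(g)))
  # tilt starts near 0 dB and grows monotonically below the reactance maximum
  expect_lt(abs(kp$tilt_db[1]), 0.1)
  x <- 2 * wavenumber(g) * effective_radius(af$area_lips_m2)
  expect_true(all(diff(kp$tilt_db[x < 2]) > 0))
})

test_that("free-field normalization is biased unless the mouth flow vanishes", {
  g <- default_grid(step = 30)
  af <- schwa_tube()
  m <- area_function_matrix(af, g)
  zr <- as_acoustic(piston_in_baffle(g, effective_radius(af$area_lips_m2)),
                    af$area_lips_m2)
  n <- environment_reciprocal(zr, mode = "monopole")
  # blocked mouth (U2 = 0): no bias, ratio is exactly H
  pb0 <- pref_bias(m, n, u2 = 0)
  expect_equal(pb0$bias, rep(1 + 0i, length(g)))
  expect_equal(pb0$ratio, pb0$h)
  # n11 = 0 (zero input impedance): no bias either
  zr0 <- impedance_spectrum(g, 0i, convention = "acoustic")
  n0 <- environment_reciprocal(zr0, mode = "monopole")
  pb1 <- pref_bias(m, n0, u2 = 1 + 0i)
  expect_equal(pb1$bias, rep(1 + 0i, length(g)))
  # free field: the bias level drifts upward with frequency
  pb <- pref_bias(m, n)
  lowband <- mean(abs(pb$bias_db[g < 1000]))
  highband <- mean(abs(pb$bias_db[g > 5000]))
  expect_gt(highband, lowband)
})

test_that("simulated pressure sets share the measurement grid and drive", {
  g <- coarse_grid()
  af <- schwa_tube()
  m <- area_function_matrix(af, g)
  zr <- as_acoustic(piston_in_baffle(g, effective_radius(af$area_lips_m2)),
                    af$area_lips_m2)
  n <- environment_reciprocal(zr, mode = "monopole")
  ps <- pressure_set(m, n)
  expect_equal(nrow(ps), length(g))
  expect_rel_equal(ps$p1 / ps$p3, transfer_direct(m, zr)$h, 1e-10)
})
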