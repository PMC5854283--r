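test_that("rigid-walled sections reduce to the lossless cos/sin form", {
  g <- coarse_grid()
  sec <- tube_section(0.123, 4.2e-4, "rigid")
  m <- uniform_tube_matrix(sec, g)
  oracle <- lossless_tube_oracle(as.numeric(g), 0.123, 4.2e-4)
  for (entry in c("m11", "m12", "m21", "m22")) {
    expect_lt(max(Mod(m[[entry]] - oracle[[entry]])) /
                max(Mod(oracle[[entry]])), 1e-12)
  }
})

test_that("zero-length sections are the identity and quarter-wave m11 vanishes", {
  g <- coarse_grid()
  m0 <- uniform_tube_matrix(tube_section(0, 3e-4, "rigid"), g)
  expect_equal(m0$m11, rep(1 + 0i, length(g)))
  expect_equal(m0$m21, rep(0i, length(g)))
  # kL = pi/2 at f = c / (4 L)
  L <- 0.170
  fq <- 343 / (4 * L)
  mq <- uniform_tube_matrix(tube_section(L, 3e-4, "rigid"), freq_grid(fq))
  expect_lt(Mod(mq$m11[1]), 1e-12)
})

test_that("wall-lossy sections remain reciprocal to 1e-9", {
  g <- coarse_grid()
  withr::local_seed(7)
  for (i in 1:10) {
    sec <- tube_section(runif(1, 0.01, 0.3), runif(1, 1e-5, 1e-3),
                        runif(1, 1e4, 1e6))
    m <- uniform_tube_matrix(sec, g)
    expect_lt(attr(reciprocity_deviation(m), "max_deviation"), 1e-9)
  }
})

test_that("splitting a section at any ratio leaves the chain matrix unchanged", {
  g <- coarse_grid()
  withr::local_seed(11)
  for (i in 1:8) {
    L <- runif(1, 0.05, 0.3); A <- runif(1, 1e-4, 8e-4)
    zw <- sample(list("rigid", "default", 2e5), 1)[[1]]
    ratio <- runif(1, 0.05, 0.95)
    whole <- area_function(tube_section(L, A, zw))
    split <- area_function(list(tube_section(L * ratio, A, zw),
                                tube_section(L * (1 - ratio), A, zw)))
    mw <- area_function_matrix(whole, g)
    ms <- area_function_matrix(split, g)
    for (entry in c("m11", "m12", "m21", "m22")) {
      expect_lt(max(Mod(mw[[entry]] - ms[[entry]])) /
                  max(Mod(mw[[entry]])), 1e-10)
    }
  }
})

test_that("side branches are unit-determinant shunts that vanish for Zb -> Inf", {
  g <- coarse_grid()
  zb <- impedance_spectrum(g, 1e12 + 0i, convention = "acoustic")
  s <- side_branch_matrix(zb)
  expect_lt(attr(reciprocity_deviation(s), "max_deviation"), 1e-12)
  expect_lt(max(Mod(s$m21)), 1e-11)
  zb0 <- impedance_spectrum(g, c(0i, rep(1 + 0i, length(g) - 1)),
                            convention = "acoustic")
  expect_error(side_branch_matrix(zb0), "shift the grid")
})

test_that("a closed side branch notches the transfer function at its quarter wave", {
  # fine grid around the expected zero of a 20 mm closed branch: c/(4 Lb)
  g <- freq_grid(seq(3000, 5500, by = 2))
  af <- piriform_demo(wall_impedance = "default")
  h <- chain_transfer_function(af, g)
  f_min <- g[which.min(Mod(h$h))]
  expect_equal(f_min, 343 / (4 * 0.02), tolerance = 0.05)
})

test_that("area-function CSV round trip preserves sections and branches", {
  af <- piriform_demo()
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_function(af, path)
  af2 <- read_area_function(path)
  expect_equal(length(af2$sections), length(af$sections))
  expect_equal(af2$total_length_m, af$total_length_m)
  expect_equal(af2$area_lips_m2, af$area_lips_m2)
  expect_equal(length(af2$branches), 1L)
  expect_equal(af2$branches[[1]]$section$length_m, 0.02)
  g <- coarse_grid()
  m1 <- area_function_matrix(af, g)
  m2 <- area_function_matrix(af2, g)
  expect_equal(m1$m11, m2$m11, tolerance = 1e-12)
})

test_that("the uniform-tube fixture has the canonical geometry", {
  af <- schwa_tube()
  expect_equal(af$total_length_m, 0.170)
  expect_equal(af$area_lips_m2, pi * 0.0138^2)
  expect_equal(af$area_lips_m2 * 1e4, 5.98, tolerance = 1e-3)
})

test_that("rigid tube with ideal open end peaks at odd quarter-wave frequencies", {
  g <- default_grid(step = 3)
  m <- area_function_matrix(schwa_tube("rigid"), g)
  zr0 <- impedance_spectrum(g, 0i, convention = "acoustic")
  h <- transfer_direct(m, zr0)
  ft <- find_formants(h, max_n = 4)
  expected <- (2 * (1:4) - 1) * 343 / (4 * 0.170)
  expect_equal(ft$frequency_hz, expected, tolerance = 3 / min(expected))
})
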