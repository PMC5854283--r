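# shared fixtures: small grids, the canonical uniform tube, and a known
# second-order resonator used as an analysis oracle

coarse_grid <- function() freq_grid(seq(50, 6000, by = 50))

schwa_area <- pi * 0.0138^2

# closed-form lossless tube chain matrix, written out independently of the
# package implementation (the plane-wave cos/sin form)
lossless_tube_oracle <- function(f, L, A, c0 = 343, rho = 1.20) {
  k <- 2 * pi * f / c0
  z0 <- rho * c0 / A
  list(m11 = as.complex(cos(k * L)),
       m12 = 1i * z0 * sin(k * L),
       m21 = 1i * sin(k * L) / z0,
       m22 = as.complex(cos(k * L)))
}

# transfer function of a single second-order resonance with unit DC gain
resonator_tf <- function(f, f0 = 500, q = 20) {
  transfer_function(f, 1 / (1 - (f / f0)^2 + 1i * f / (f0 * q)),
                    provenance = "chain_matrix")
}

# random reciprocal 2x2 series: draw three entries, set the fourth so that
# the determinant is exactly 1
random_reciprocal_tm <- function(f, seed) {
  withr::local_seed(seed)
  n <- length(f)
  draw <- function() complex(real = stats::rnorm(n, sd = 1),
                             imaginary = stats::rnorm(n, sd = 1))
  m11 <- draw() + 2  # keep away from zero
  m12 <- draw(); m21 <- draw()
  m22 <- (1 + m12 * m21) / m11
  tm_series(f, m11, m12, m21, m22)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(Mod(x - y) / pmax(Mod(y), .Machine$double.xmin)), tol)
}
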