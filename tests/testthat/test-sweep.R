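# sweep tests use short sweeps; the full 21 s measurement is exercised by
# the acceptance tests

short_spec <- function() sweep_spec(duration = 3)

test_that("the sweep starts at f_start, ends at f_end and keeps unit envelope", {
  sp <- short_spec()
  sw <- farina_sweep(sp)
  fs <- sp$sample_rate
  # frequency from the span between the first/last few zero crossings
  crossings <- which(diff(sign(sw$samples)) != 0) / fs
  zc_freq <- function(tc) (length(tc) - 1) / (2 * (tc[length(tc)] - tc[1]))
  expect_equal(zc_freq(crossings[1:7]), sp$f_start, tolerance = 0.03)
  nzc <- length(crossings)
  expect_equal(zc_freq(crossings[(nzc - 40):nzc]), sp$f_end,
               tolerance = 0.02)
  n <- length(sw$samples)
  # constant envelope: every 10 ms window reaches an extremum near +-1
  win <- matrix(sw$samples[1:(floor(n / 480) * 480)], nrow = 480)
  expect_true(all(apply(abs(win), 2, max) > 0.97))
})

test_that("the sweep magnitude spectrum falls 3 dB per octave across the band", {
  sp <- short_spec()
  sw <- farina_sweep(sp)
  n <- length(sw$samples)
  spec <- Mod(stats::fft(sw$samples))[1:(n %/% 2)]
  f <- (seq_len(n %/% 2) - 1) * sp$sample_rate / n
  band_level <- function(fc) {
    sel <- f > fc / 2^0.25 & f < fc * 2^0.25
    20 * log10(mean(spec[sel]))
  }
  centers <- c(400, 800, 1600, 3200)
  levels <- vapply(centers, band_level, numeric(1))
  slopes <- diff(levels)  # per octave
  expect_true(all(abs(slopes + 3) < 1))
})

test_that("deconvolving the sweep against itself gives a flat in-band response", {
  sp <- short_spec()
  sw <- farina_sweep(sp)
  d <- deconvolve(sw, sw)
  inb <- d$frf$frequency_hz >= 150 & d$frf$frequency_hz <= 8000
  expect_lt(max(abs(d$frf$mag_db[inb])), 0.1)
})

test_that("a known second-order resonator deconvolves to its closed form", {
  sp <- short_spec()
  sw <- farina_sweep(sp)
  fs <- sp$sample_rate
  hres <- function(fq) 1 / (1 - (fq / 500)^2 + 1i * fq / (500 * 20))
  ir <- tracttf:::frf_to_impulse(hres, 2^16, fs, sp$f_start, sp$f_end)
  y <- tracttf:::fft_convolve(sw$samples, ir)
  rec <- recording(y[1:(length(sw$samples) + 2^15)], fs, "P1")
  d <- deconvolve(rec, sw)
  inb <- d$frf$frequency_hz >= 150 & d$frf$frequency_hz <= 8000
  err <- d$frf$mag_db[inb] -
    20 * log10(Mod(hres(d$frf$frequency_hz[inb])))
  expect_lt(max(abs(err)), 0.1)

  # additive noise at 60 dB SNR: the response stays within 0.5 dB wherever
  # the resonator response is within 30 dB of its peak (below that the
  # per-bin noise floor, not the method, sets the error)
  withr::local_seed(17)
  noisy <- recording(rec$samples + stats::rnorm(length(rec$samples),
                                                sd = stats::sd(rec$samples) / 1000),
                     fs, "P1")
  dn <- deconvolve(noisy, sw)
  truth <- 20 * log10(Mod(hres(dn$frf$frequency_hz)))
  strong <- inb & truth > max(truth) - 30
  errn <- dn$frf$mag_db[strong] - truth[strong]
  expect_lt(max(abs(errn)), 0.5)
})

test_that("sample-rate mismatches are rejected", {
  sw <- farina_sweep(short_spec())
  rec <- recording(sw$samples, 44100, "P1")
  expect_error(deconvolve(rec, sw), "sample-rate mismatch")
})

test_that("noiseless virtual measurements recover the true transfer function", {
  sp <- short_spec()
  vm <- virtual_measurement(schwa_tube(), sp)
  h <- measured_transfer_function(vm, f_low = 150, f_high = 6000)
  h_true <- chain_transfer_function(schwa_tube(), freq_grid(h$frequency_hz))
  err <- tf_mag_db(h) - tf_mag_db(h_true)
  expect_lt(max(abs(err)), 0.2)
})

test_that("virtual measurements are deterministic per seed and scale-invariant", {
  sp <- sweep_spec(duration = 1.5)
  vm1 <- virtual_measurement(schwa_tube(), sp, snr_db = 60, seed = 4)
  vm2 <- virtual_measurement(schwa_tube(), sp, snr_db = 60, seed = 4)
  expect_identical(vm1$p1$samples, vm2$p1$samples)
  vm3 <- virtual_measurement(schwa_tube(), sp, snr_db = 60, seed = 5)
  expect_false(identical(vm3$p1$samples, vm1$p1$samples))

  # scaling the excitation amplitude cancels exactly in P1/P3
  vm <- virtual_measurement(schwa_tube(), sp)
  vm_scaled <- vm
  vm_scaled$p1$samples <- vm$p1$samples * 3.7
  vm_scaled$p3$samples <- vm$p3$samples * 3.7
  h1 <- measured_transfer_function(vm)
  h2 <- measured_transfer_function(vm_scaled)
  expect_lt(max(abs(tf_mag_db(h1) - tf_mag_db(h2))), 1e-6)
})

test_that("the round trip recovers random multi-resonance responses in band", {
  sp <- sweep_spec(duration = 2)
  fs <- sp$sample_rate
  sw <- farina_sweep(sp)
  withr::local_seed(31)
  for (rep in 1:3) {
    f0s <- sort(stats::runif(3, 300, 4000))
    qs <- stats::runif(3, 5, 25)
    hfun <- function(fq) {
      h <- rep(1 + 0i, length(fq))
      for (i in 1:3) h <- h / (1 - (fq / f0s[i])^2 + 1i * fq / (f0s[i] * qs[i]))
      h
    }
    ir <- tracttf:::frf_to_impulse(hfun, 2^16, fs, sp$f_start, sp$f_end)
    y <- tracttf:::fft_convolve(sw$samples, ir)
    rec <- recording(y[1:(length(sw$samples) + 2^15)], fs, "sys")
    d <- deconvolve(rec, sw)
    truth <- 20 * log10(Mod(hfun(d$frf$frequency_hz)))
    # compare where the response carries energy (within 40 dB of its peak);
    # far below that the deconvolution floor dominates any response
    keep <- d$frf$frequency_hz >= 150 & d$frf$frequency_hz <= 6000 &
      truth > max(truth) - 40
    err <- d$frf$mag_db[keep] - truth[keep]
    expect_lt(max(abs(err)), 0.2)
  }
})

test_that("WAV round trip is exact for float32 and labels channels by suffix", {
  sw <- farina_sweep(sweep_spec(duration = 0.1))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "take1_p3.wav")
  write_wav(sw, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, sw$sample_rate)
  expect_equal(back$label, "P3")
  # float32 quantization only
  expect_lt(max(abs(back$samples - sw$samples)), 1e-7)
})
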