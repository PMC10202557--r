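test_that("band table is the canonical five-band partition of 2-44 Hz", {
  b <- defaultBands()
  expect_named(b, c("delta", "theta", "alpha", "beta", "gamma"))
  edges <- do.call(rbind, b)
  expect_true(all(edges[, 1] < edges[, 2]))
  expect_true(all(edges >= 2 & edges <= 44))
  # half-open bands must not overlap
  for (i in 1:4) expect_lte(edges[i, 2], edges[i + 1, 1])
})

test_that("quarter-cycle lag and period follow 1/f", {
  expect_equal(quarterCycleLag(10), 25)
  expect_equal(quarterCycleLag(20), 12.5)
  expect_equal(oscillationPeriod(10), 100)
  expect_error(quarterCycleLag(0))
})

test_that("band-pass filter is zero-phase and has the right pass/stop bands", {
  fs <- 128; n <- fs * 8
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 10 * t)
  y <- oscloop:::fftBandpass(x, fs, 2, 44)
  # zero phase: cross-correlation peaks at lag 0
  cc <- ccf(x, y, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_equal(sqrt(mean(y^2)), sqrt(mean(x^2)), tolerance = 0.02)
  # stop band
  z <- oscloop:::fftBandpass(sin(2 * pi * 55 * t), fs, 2, 44)
  expect_lt(sqrt(mean(z^2)), 0.01)
})

test_that("FFT resampling preserves in-band sinusoids", {
  fs <- 500; t <- seq_len(fs * 5) / fs
  x <- sin(2 * pi * 10 * t)
  y <- oscloop:::fftResample(x, fs, 128)
  expect_length(y, 128 * 5)
  expect_equal(sqrt(2 * mean(y^2)), 1, tolerance = 0.02)
  p <- Mod(fft(y))^2
  f <- abs(oscloop:::fftFreqs(length(y), 128))
  expect_equal(f[which.max(p[-1]) + 1], 10, tolerance = 0.1)
})

test_that("narrowband noise concentrates its power in band", {
  set.seed(7)
  x <- oscloop:::narrowbandNoise(128 * 60, 128, 4, 7.5)
  expect_gte(oscloop:::bandPowerFraction(as.vector(x), 128, 4, 7.5), 0.9)
  g <- oscloop:::narrowbandNoise(128 * 60, 128, 30.5, 44)
  expect_gte(oscloop:::bandPowerFraction(as.vector(g), 128, 30.5, 44), 0.9)
  expect_equal(mean(x^2), 1, tolerance = 1e-9)  # unit RMS normalization
})

test_that("analytic signal gives the quadrature pair of a sinusoid", {
  fs <- 128; t <- seq_len(fs * 4) / fs
  a <- oscloop:::analyticSignal(cos(2 * pi * 8 * t))
  expect_equal(Re(a), cos(2 * pi * 8 * t), tolerance = 1e-10)
  expect_equal(Im(a), sin(2 * pi * 8 * t), tolerance = 1e-6)
  expect_equal(Mod(a), rep(1, length(t)), tolerance = 1e-6)
})
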