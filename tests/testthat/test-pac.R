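test_that("band PC1 handles rank-1, isotropic and rotated inputs", {
  set.seed(51)
  fs <- 128; n <- fs * 10
  s <- as.vector(oscloop:::narrowbandNoise(n, fs, 4, 7.5))
  w <- c(0.48, -0.6, 0.64)
  pc <- bandPC1(outer(w, s), fs, c(4, 7.5))
  expect_gte(attr(pc, "varExplained"), 0.999)
  expect_gt(abs(cor(pc, s)), 0.99)
  # isotropic noise: leading eigenvalue near 1/3 of total
  iso <- matrix(rnorm(3 * 20000), 3)
  pciso <- bandPC1(iso, fs, NULL)
  expect_equal(attr(pciso, "varExplained"), 1 / 3, tolerance = 0.05)
  # rotation invariance up to sign
  R <- diag(3)[c(2, 3, 1), ] * c(1, -1, 1)
  xyz <- outer(w, s) + matrix(rnorm(3 * n), 3) * 0.05
  p1 <- bandPC1(xyz, fs, c(4, 7.5))
  p2 <- bandPC1(R %*% xyz, fs, c(4, 7.5))
  expect_gt(abs(cor(p1, p2)), 0.9999)
  expect_error(bandPC1(matrix(0, 3, 100), fs), "zero")
})

test_that("mean vector length recovers the planted modulation depth m/2", {
  fs <- 128; n <- fs * 300
  for (m in c(0.5, 1.0)) {
    pp <- plantedPacPair(n, fs, m, seed = round(10 * m))
    r <- pacMvl(pp$theta, pp$gamma, fs)
    expect_equal(r$mvl, m / 2, tolerance = 0.05)
  }
  # constant envelope: no modulation
  t <- seq_len(n) / fs
  flat <- pacMvl(plantedPacPair(n, fs, 0, seed = 3)$theta,
                 cos(2 * pi * 38 * t), fs)
  expect_lt(flat$mvl, 0.02)
  expect_error(pacMvl(rnorm(100), rnorm(99), fs), "lengths")
})

test_that("mvl is invariant to gamma amplitude scaling", {
  fs <- 128; n <- fs * 60
  pp <- plantedPacPair(n, fs, 0.6, seed = 5)
  a <- pacMvl(pp$theta, pp$gamma, fs)$mvl
  b <- pacMvl(pp$theta, 7.3 * pp$gamma, fs)$mvl
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("surrogate z-scores separate coupled from independent series", {
  fs <- 128; n <- fs * 120
  pp <- plantedPacPair(n, fs, 0.8, seed = 6)
  zc <- pacZscore(pp$theta, pp$gamma, fs, n_surrogates = 200, seed = 1)
  expect_gt(zc$z, 5)
  set.seed(7)
  g0 <- as.vector(oscloop:::narrowbandNoise(n, fs, 30.5, 44))
  z0 <- pacZscore(pp$theta, g0, fs, n_surrogates = 200, seed = 1)
  expect_lt(abs(z0$z), 3)
  # determinism under the seed
  z1 <- pacZscore(pp$theta, pp$gamma, fs, n_surrogates = 200, seed = 9)
  z2 <- pacZscore(pp$theta, pp$gamma, fs, n_surrogates = 200, seed = 9)
  expect_identical(z1$z, z2$z)
  expect_error(pacZscore(pp$theta, pp$gamma, fs, n_surrogates = 50), "200")
  expect_error(pacZscore(rnorm(100), rnorm(100), fs), "2 s")
})

test_that("the FFT surrogate shortcut equals explicit circular shifting", {
  fs <- 128; n <- fs * 30
  pp <- plantedPacPair(n, fs, 0.5, seed = 8)
  ph <- Arg(oscloop:::analyticSignal(pp$theta))
  env <- Mod(oscloop:::analyticSignal(pp$gamma))
  keep <- oscloop:::pacTrimIndex(n, fs)
  ph <- ph[keep]; env <- env[keep]
  nn <- length(ph)
  z <- exp(1i * ph)
  C <- fft(fft(env) * Conj(fft(Conj(z))), inverse = TRUE) / nn
  for (s in c(200, 1000, 2000)) {
    direct <- Mod(sum(env[((seq_len(nn) + s - 1) %% nn) + 1] * z)) / sum(env)
    expect_equal(Mod(C[s + 1]) / sum(env), direct, tolerance = 1e-10)
  }
})

test_that("pacTable reports one row per ROI with finite statistics", {
  set.seed(9)
  fs <- 128; n <- fs * 30
  xyz <- replicate(2, {
    s <- as.vector(oscloop:::narrowbandNoise(n, fs, 2, 44))
    outer(c(1, 0.5, -0.2), s)
  }, simplify = FALSE)
  names(xyz) <- c("lAUD", "rAUD")
  tab <- pacTable(xyz, fs, seed = 2)
  expect_equal(tab$roi, c("lAUD", "rAUD"))
  expect_true(all(is.finite(tab$z)))
  expect_true(all(tab$mvl >= 0))
})
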