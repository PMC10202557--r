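test_that("lagged phase coherence follows its closed form", {
  expect_equal(laggedPhaseCoherence(0.5i), 0.25)
  expect_equal(laggedPhaseCoherence(0.6 + 0i), 0)
  expect_equal(laggedPhaseCoherence(0.3 + 0.4i), 0.16 / 0.91)
  expect_warning(v <- laggedPhaseCoherence(1 + 0i), "zero-lag")
  expect_equal(v, 0)
})

test_that("a quarter-period delay at band centre gives arg(c) near -pi/2", {
  fs <- 128; n <- fs * 120
  set.seed(31)
  f0 <- 10
  s <- as.vector(oscloop:::narrowbandNoise(n, fs, 9.5, 10.5))
  lag <- round(fs / (4 * f0))          # quarter period
  x <- s + rnorm(n) * 0.05
  y <- c(rep(0, lag), s[1:(n - lag)]) + rnorm(n) * 0.05
  cs <- epochCrossSpectra(rbind(a = x, b = y), epoch_len_s = 4,
                          bands = list(a10 = c(9.5, 10.75)),
                          amp_reject_uV = Inf, fs = fs)
  co <- complexCoherency(cs, "a", "b", "a10")
  # a pure delay contributes a quarter-cycle phase; its sign is fixed by the
  # S_xy = E[X conj(Y)] convention
  expect_lt(abs(abs(Arg(co$c)) - pi / 2), 0.3)
  expect_gt(laggedPhaseCoherence(co), 0.5)
})

test_that("coherency of independent channels is small and LPC symmetric", {
  set.seed(32)
  cs <- epochCrossSpectra(matrix(rnorm(2 * 128 * 512), 2,
                                 dimnames = list(c("a", "b"), NULL)),
                          amp_reject_uV = Inf, fs = 128)
  cab <- complexCoherency(cs, "a", "b", "theta")
  cba <- complexCoherency(cs, "b", "a", "theta")
  expect_lt(Mod(cab$c), 0.3)
  expect_equal(laggedPhaseCoherence(cab), laggedPhaseCoherence(cba))
  expect_gte(laggedPhaseCoherence(cab), 0)
  expect_lt(laggedPhaseCoherence(cab), 1)
})

test_that("instantaneous mixtures of one source are nulled by LPC but not coherence", {
  set.seed(33)
  fs <- 128; n <- fs * 64
  hits <- 0; cohs <- numeric(10)
  for (r in 1:10) {
    s <- as.vector(oscloop:::narrowbandNoise(n, fs, 8, 12))
    x <- scalpMixture(cbind(s), matrix(c(1, 0.8), 2), noise_sd = 0.3)
    rownames(x) <- c("a", "b")
    cs <- epochCrossSpectra(x, bands = list(alpha = c(8, 12)),
                            amp_reject_uV = Inf, fs = fs)
    cohs[r] <- Mod(complexCoherency(cs, "a", "b", "alpha",
                                    form = "coherence")$c)^2
    p <- lpcSignificance(cs, "a", "b", "alpha", n_shuffles = 200,
                         seed = r)$p
    if (p >= 0.05) hits <- hits + 1
  }
  expect_true(all(cohs > 0.5))
  expect_gte(hits, 8)                  # LPC stays non-significant
})

test_that("surrogate p-values detect genuine lagged coupling", {
  set.seed(34)
  fs <- 128; n <- fs * 120
  s <- as.vector(oscloop:::narrowbandNoise(n, fs, 9.5, 10.5))
  lag <- round(0.025 * fs)             # 25 ms delay at 10 Hz
  x <- s + rnorm(n) * 0.2
  y <- c(rep(0, lag), s[1:(n - lag)]) + rnorm(n) * 0.2
  cs <- epochCrossSpectra(rbind(a = x, b = y),
                          bands = list(alpha = c(8, 12)),
                          amp_reject_uV = Inf, fs = fs)
  r <- lpcSignificance(cs, "a", "b", "alpha", n_shuffles = 200, seed = 1)
  expect_lt(r$p, 0.05)
  # asymptotic route agrees on the obvious case
  ra <- lpcSignificance(cs, "a", "b", "alpha", method = "asymptotic")
  expect_lt(ra$p, 0.05)
})

test_that("input validation catches degenerate requests", {
  set.seed(35)
  cs <- epochCrossSpectra(matrix(rnorm(2 * 128 * 24), 2,
                                 dimnames = list(c("a", "b"), NULL)),
                          amp_reject_uV = Inf, fs = 128)
  expect_error(complexCoherency(cs, "a", "a", "theta"), "distinct")
  expect_error(complexCoherency(cs, "a", "b", "mu"), "band")
  expect_error(lpcSignificance(cs, "a", "b", "theta"), "8 epochs")
  tab <- lpcTable(cs, bands = "theta")
  expect_equal(nrow(tab), 1)
  expect_true(all(tab$lpc >= 0 & tab$lpc < 1))
})
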