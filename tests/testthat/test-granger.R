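test_that("MVAR least squares recovers known AR coefficients", {
  set.seed(41)
  n <- 1e4
  A1 <- matrix(c(0.5, 0.2, 0, 0.3), 2, 2, byrow = TRUE)
  A3 <- matrix(c(-0.2, 0, 0.1, 0.1), 2, 2, byrow = TRUE)
  x <- matrix(0, n, 2)
  e <- matrix(rnorm(2 * n), n, 2)
  for (t in 4:n)
    x[t, ] <- A1 %*% x[t - 1, ] + A3 %*% x[t - 3, ] + e[t, ]
  fit <- fitMVAR(x, order = 3)
  se <- sqrt(diag(fit$Sigma)[1] / n)   # crude scale for coefficient error
  expect_lt(max(abs(fit$A[, , 1] - A1)), 3 * se * 5)
  expect_lt(max(abs(fit$A[, , 3] - A3)), 3 * se * 5)
  expect_true(fit$stable)
})

test_that("auto order selection stays small for white noise", {
  set.seed(42)
  x <- matrix(rnorm(4000), ncol = 2)
  fit <- fitMVAR(x, order = "auto", pmax = 10)
  expect_lte(fit$p, 3)
  offdiag <- fit$Sigma[1, 2] / sqrt(prod(diag(fit$Sigma)))
  expect_lt(abs(offdiag), 0.1)
  expect_error(fitMVAR(x[1:30, ], order = 5), "short")
})

test_that("time-domain GC matches the ln(1.25) closed form", {
  set.seed(43)
  n <- 3e4
  x <- rnorm(n); e <- rnorm(n)
  y <- c(0, 0.5 * x[-n]) + e
  expect_equal(as.numeric(grangerPair(x, y, order = 3)), log(1.25),
               tolerance = 0.05)
  expect_lt(as.numeric(grangerPair(y, x, order = 3)), 0.01)
})

test_that("GC is invariant under channel rescaling and floored at zero", {
  set.seed(44)
  n <- 1e4
  x <- rnorm(n); y <- c(0, 0.4 * x[-n]) + rnorm(n)
  g1 <- as.numeric(grangerPair(x, y, order = 2))
  g2 <- as.numeric(grangerPair(5 * x, 0.1 * y, order = 2))
  expect_equal(g1, g2, tolerance = 1e-8)
  g0 <- grangerPair(rnorm(3000), rnorm(3000), order = 2)
  expect_gte(as.numeric(g0), 0)
  expect_type(attr(g0, "floored"), "logical")
})

test_that("band-restricted GC agrees with both directions from one fit", {
  set.seed(45)
  n <- 2e4
  x <- rnorm(n); y <- c(0, 0.5 * x[-n]) + rnorm(n)
  gb <- oscloop:::gewekeBoth(x, y, order = 3, band = c(4, 7.5), fs = 128)
  g1 <- grangerPair(x, y, order = 3, band = c(4, 7.5), fs = 128)
  g2 <- grangerPair(y, x, order = 3, band = c(4, 7.5), fs = 128)
  expect_equal(unname(gb["fwd"]), as.numeric(g1))
  expect_equal(unname(gb["rev"]), as.numeric(g2))
  expect_error(grangerPair(x, y, order = 3, band = c(60, 70), fs = 128),
               "Nyquist")
})

test_that("a planted lagged theta edge is directional on source series", {
  set.seed(46)
  fs <- 128; n <- fs * 120
  fwd <- rev <- numeric(8)
  for (r in 1:8) {
    b <- oscloop:::narrowbandNoise(n, fs, 4, 7.5, ncol = 2)
    x <- oscloop:::applyCoupling(
      b, data.frame(source = "A", target = "B", band = "theta",
                    strength = 0.5, lag = 3L), c("A", "B"))
    x <- x + oscloop:::pinkNoise(n, fs, 2, 44, ncol = 2) * 0.3
    fwd[r] <- as.numeric(grangerPair(x[, 1], x[, 2], order = 12,
                                     band = c(4, 7.5), fs = fs))
    rev[r] <- as.numeric(grangerPair(x[, 2], x[, 1], order = 12,
                                     band = c(4, 7.5), fs = fs))
  }
  expect_true(all(fwd > rev))
  expect_lt(median(rev), 0.2 * median(fwd))
})

test_that("the directed roster is complete and gcTable fills it once each", {
  roster <- gcLinkRoster()
  expect_equal(nrow(roster), 22)
  expect_false(any(duplicated(paste(roster$source, roster$target))))
  expect_true(all(roster$source != roster$target))
  # 12 pgACC links, 8 within-hemisphere sensory links, 2 interhemispheric
  expect_equal(sum(roster$source == "pgACC" | roster$target == "pgACC"), 12)
  set.seed(47)
  fs <- 128
  series <- replicate(7, as.vector(oscloop:::narrowbandNoise(fs * 30, fs, 2, 44)),
                      simplify = FALSE)
  names(series) <- c("lAUD", "rAUD", "lSOM", "rSOM", "lPHC", "rPHC", "pgACC")
  tab <- gcTable(series, fs, order = 6)
  expect_equal(nrow(tab), 22)
  expect_true(all(tab$gc >= 0))
  expect_error(gcTable(series[-1], fs), "lAUD")
})

test_that("source-level condition templates reproduce the directed loop pattern", {
  fs <- 128
  conds <- c("control", "tinnitus", "pain")
  mu <- matrix(0, 4, 3, dimnames = list(
    c("PHCtoSOM", "SOMtoPHC", "PHCtoAUD", "AUDtoPHC"), conds))
  for (cond in conds) {
    for (s in 1:3) {
      sim <- simulateSubject(makeGroupTemplate(cond), duration_s = 90,
                             fs = fs, seed = 900 + s)
      cur <- sim$sources@currents
      rois <- sim$sources@rois
      atlas <- defaultROIs()
      ser <- function(r) {
        d <- as.numeric(atlas[match(r, atlas$roi), c("x", "y", "z")])
        d <- d / sqrt(sum(d^2))
        colSums(cur[match(r, rois), , ] * d)
      }
      g <- function(a, b) as.numeric(grangerPair(ser(a), ser(b), order = 12,
                                                 band = c(4, 7.5), fs = fs))
      mu[, cond] <- mu[, cond] + c(g("lPHC", "lSOM"), g("lSOM", "lPHC"),
                                   g("lPHC", "lAUD"), g("lAUD", "lPHC")) / 3
    }
  }
  # control: near-null everywhere
  expect_true(all(mu[, "control"] < 0.02))
  # tinnitus: PHC drives SOM unidirectionally, PHC and AUD couple both ways
  expect_gt(mu["PHCtoSOM", "tinnitus"], 2 * mu["SOMtoPHC", "tinnitus"])
  expect_gt(mu["PHCtoAUD", "tinnitus"], 3 * mu["PHCtoAUD", "control"])
  expect_gt(mu["AUDtoPHC", "tinnitus"], 3 * mu["AUDtoPHC", "control"])
  # pain: the mirror image
  expect_gt(mu["PHCtoAUD", "pain"], 2 * mu["AUDtoPHC", "pain"])
  expect_gt(mu["PHCtoSOM", "pain"], 3 * mu["PHCtoSOM", "control"])
  expect_gt(mu["SOMtoPHC", "pain"], 3 * mu["SOMtoPHC", "control"])
})
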