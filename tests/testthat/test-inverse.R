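test_that("noise-free point sources localize exactly (spot checks)", {
  set.seed(21)
  lf <- miniLeadField(); op <- miniOperator()
  G <- gainMatrix(lf)
  for (v in sample(160, 25)) {
    q <- rnorm(3)
    phi <- G[, (3 * v - 2):(3 * v)] %*% q
    pw <- standardizedPower(op, applyInverse(op, matrix(phi, ncol = 1)))
    expect_equal(which.max(pw), v)
  }
})

test_that("the same holds for a synthetic (random) lead field at alpha -> 0", {
  set.seed(22)
  lf <- buildLeadField(mont19, miniSpace(), model = "synthetic", seed = 3)
  op <- sloretaOperator(lf, alpha = 0)
  G <- gainMatrix(lf)
  for (v in sample(160, 15)) {
    q <- rnorm(3)
    phi <- G[, (3 * v - 2):(3 * v)] %*% q
    pw <- standardizedPower(op, applyInverse(op, matrix(phi, ncol = 1)))
    expect_equal(which.max(pw), v)
  }
})

test_that("the inverse is linear and standardized power is quadratic", {
  set.seed(23)
  op <- miniOperator()
  p1 <- matrix(rnorm(19), ncol = 1); p2 <- matrix(rnorm(19), ncol = 1)
  j1 <- applyInverse(op, p1)@j; j2 <- applyInverse(op, p2)@j
  j <- applyInverse(op, 2 * p1 - 3 * p2)@j
  expect_equal(j, 2 * j1 - 3 * j2, tolerance = 1e-10)
  pw1 <- standardizedPower(op, applyInverse(op, p1))
  pw4 <- standardizedPower(op, applyInverse(op, 2 * p1))
  expect_equal(pw4, 4 * pw1, tolerance = 1e-10)
  # phi = 0 -> all zero
  expect_true(all(standardizedPower(op, applyInverse(op, matrix(0, 19, 1))) == 0))
  # single sample in, single sample out
  expect_equal(ncol(applyInverse(op, p1)@j), 1)
})

test_that("montage and reference contracts are enforced", {
  op <- miniOperator()
  rec <- randomRecording(256)
  expect_error(applyInverse(op, rec), "common")
  bad <- commonAverageReference(rec)
  bad@channelLabels[1] <- "Oz"
  expect_error(applyInverse(op, bad), "mismatch")
})

test_that("uniform voxel power gives log relative power ln(1/N) everywhere", {
  sp <- miniSpace()
  n <- 128 * 8
  set.seed(24)
  s <- as.vector(oscloop:::narrowbandNoise(n, 128, 4, 7.5))
  j <- matrix(rep(s, each = 3 * 160), 3 * 160, n) *
    rep(c(1, 0, 0), 160)               # same series, x-orientation, all voxels
  cd <- new("CurrentDensity", j = j, fs = 128, nVoxels = 160)
  pw <- roiBandPower(cd, sp, defaultBands()["theta"])
  expect_equal(as.vector(pw), rep(log(1 / 160), 7), tolerance = 1e-9)
})

test_that("relative power is invariant under global amplitude scaling", {
  set.seed(25)
  sp <- miniSpace()
  cd <- new("CurrentDensity", j = matrix(rnorm(480 * 512), 480), fs = 128,
            nVoxels = 160)
  cd2 <- cd; cd2@j <- 2 * cd@j
  expect_equal(roiBandPower(cd, sp), roiBandPower(cd2, sp), tolerance = 1e-12)
  silent <- cd; silent@j[] <- 0
  expect_error(roiBandPower(silent, sp), "silent")
})

test_that("ROI series are the rows of the ROI voxel and PC1 catches a planted orientation", {
  set.seed(26)
  sp <- miniSpace()
  j <- matrix(rnorm(480 * 512), 480)
  cd <- new("CurrentDensity", j = j, fs = 128, nVoxels = 160)
  ts <- roiTimeSeries(cd, sp)
  v <- roiTable(sp)$voxel[1]
  expect_equal(ts[[1]], j[(3 * v - 2):(3 * v), ])
  # single-orientation source: PC1 captures ~all variance
  s <- as.vector(oscloop:::narrowbandNoise(512, 128, 4, 7.5))
  xyz <- outer(c(0.6, -0.64, 0.48), s)
  pc <- bandPC1(xyz, 128, c(4, 7.5))
  expect_gte(attr(pc, "varExplained"), 0.999)
})
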