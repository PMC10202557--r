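test_that("equal-conductivity shells reduce to the homogeneous-sphere series", {
  tn <- oscloop:::shellTransfer(c(78, 86, 92), c(1, 1, 1), 60)
  n <- 1:60
  expect_equal(tn, (2 * n + 1) / n, tolerance = 1e-12)
})

test_that("free-medium expansion matches the direct dipole potential", {
  set.seed(2)
  f <- 40
  p <- c(0.3, -0.5, 0.81); p <- p / sqrt(sum(p^2)) * f
  q <- c(0.2, 0.7, -0.4)
  eDir <- standard1020Positions(1)
  rObs <- eDir * 92
  nmax <- 80; ns <- 1:nmax
  zh <- p / f
  xh <- c(0, 0, 1) - sum(c(0, 0, 1) * zh) * zh; xh <- xh / sqrt(sum(xh^2))
  yh <- c(zh[2] * xh[3] - zh[3] * xh[2], zh[3] * xh[1] - zh[1] * xh[3],
          zh[1] * xh[2] - zh[2] * xh[1])
  cg <- as.vector(eDir %*% zh); sg <- sqrt(pmax(0, 1 - cg^2))
  cph1 <- ifelse(sg > 1e-12, as.vector(eDir %*% xh) / sg, 0)
  cph2 <- ifelse(sg > 1e-12, as.vector(eDir %*% yh) / sg, 0)
  L <- oscloop:::legendreP01(cg, nmax)
  rc <- f^(ns - 1) * 92^-(ns + 1) / (4 * pi)
  Vser <- sum(q * zh) * as.vector(t(L$P) %*% (rc * ns)) -
    sum(q * xh) * as.vector(t(L$P1) %*% rc) * cph1 -
    sum(q * yh) * as.vector(t(L$P1) %*% rc) * cph2
  Vdir <- unname(oscloop:::infiniteMediumPotential(rObs, p, q))
  expect_equal(Vser, Vdir, tolerance = 1e-10)
})

test_that("skull conductivity attenuates high spatial frequencies", {
  tn <- oscloop:::shellTransfer(c(78, 86, 92), c(1, 1 / 80, 1), 30)
  t0 <- oscloop:::shellTransfer(c(78, 86, 92), c(1, 1, 1), 30)
  ratio <- tn / t0
  expect_true(all(ratio > 0 & ratio < 1))
  expect_true(all(diff(ratio) < 0))   # monotone low-pass in degree
})

test_that("grid presets have their exact voxel counts and distinct ROI voxels", {
  sp <- miniSpace()
  expect_equal(nrow(voxelCoords(sp)), 160)
  expect_equal(nrow(voxelCoords(solutionSpace("test"))), 500)
  roi <- roiTable(sp)
  expect_equal(nrow(roi), 7)
  expect_false(anyDuplicated(roi$voxel) > 0)
  expect_true(all(sqrt(rowSums(voxelCoords(sp)^2)) <= 78))
})

test_that("forward columns are the potentials of unit dipoles", {
  lf <- miniLeadField()
  G <- gainMatrix(lf)
  expect_equal(dim(G), c(19, 3 * 160))
  expect_true(all(is.finite(G)))
  # average over electrodes need not vanish, but the pattern must be
  # non-trivial for every voxel
  expect_true(all(colSums(abs(G)) > 0))
})

test_that("synthetic lead field is seed-reproducible", {
  sp <- miniSpace()
  a <- buildLeadField(mont19, sp, model = "synthetic", seed = 5)
  b <- buildLeadField(mont19, sp, model = "synthetic", seed = 5)
  d <- buildLeadField(mont19, sp, model = "synthetic", seed = 6)
  expect_identical(gainMatrix(a), gainMatrix(b))
  expect_false(identical(gainMatrix(a), gainMatrix(d)))
})

test_that("voxels outside the brain shell are rejected", {
  sp <- miniSpace()
  sp@coords[1, ] <- c(85, 0, 0)
  expect_error(buildLeadField(mont19, sp), "innermost")
})
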