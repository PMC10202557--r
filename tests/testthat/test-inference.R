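test_that("one-way F and eta-squared match hand-computed sums of squares", {
  r <- voxelwiseLogF(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                     c("a", "a", "a", "b", "b", "b"))
  expect_equal(unname(r$F), 13.5)
  expect_equal(unname(r$logF), log(13.5))
  # three balanced groups 1:3 / 4:6 / 7:9: SSB 54, SSW 6
  e2 <- etaSquared(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(e2, 54 / 60)
  expect_error(voxelwiseLogF(matrix(rep(1, 6), ncol = 1),
                             rep(c("a", "b"), each = 3)), "variance")
})

test_that("permutation max-statistic assigns the minimum p to a huge effect", {
  set.seed(61)
  y <- matrix(rnorm(30 * 10), 30, 10)
  g <- rep(c("a", "b", "c"), each = 10)
  y[g == "b", 4] <- y[g == "b", 4] + 50
  r <- permutationMaxstat(y, g, n_perm = 200, seed = 2)
  expect_equal(r$pCorr[4], 1 / 201)
  expect_true(all(r$pCorr[-4] > 0.05))
  r2 <- permutationMaxstat(y, g, n_perm = 200, seed = 2)
  expect_identical(r$maxNull, r2$maxNull)   # seeded determinism
  expect_error(permutationMaxstat(y, g, n_perm = 50), "100")
})

test_that("conjunction follows the minimum rule and is commutative", {
  r <- conjunctionMin(c(2.5, 2.5), c(1.0, 2.2))
  expect_equal(r$minZ, c(1.0, 2.2))
  expect_equal(r$significant, c(FALSE, TRUE))
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(conjunctionMin(a, b)$minZ, conjunctionMin(b, a)$minZ)
  # bounded above by each input's significance
  expect_true(all(conjunctionMin(a, b)$minZ <= a))
  expect_error(conjunctionMin(a, b[-1]), "grids")
})

test_that("contrast Z maps are signed by group direction", {
  set.seed(62)
  y <- matrix(rnorm(40 * 3), 40, 3)
  g <- factor(rep(c("control", "pat"), each = 20), levels = c("control", "pat"))
  y[21:40, 1] <- y[21:40, 1] + 3    # pat above control
  y[21:40, 2] <- y[21:40, 2] - 3    # pat below control
  z <- contrastZ(y, g, n_perm = 300, seed = 1)
  expect_gt(z[1], 1.96)
  expect_lt(z[2], -1.96)
  expect_lt(abs(z[3]), 2.5)
})

test_that("Holm-Bonferroni equals the closure-principle enumeration", {
  expect_equal(holmBonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmBonferroni(0.2), 0.2)
  expect_equal(holmBonferroni(rep(1, 4)), rep(1, 4))
  expect_error(holmBonferroni(c(0.5, 1.2)), "0, 1")
  set.seed(63)
  for (i in 1:25) {
    m <- sample(2:8, 1)
    p <- runif(m)
    adj <- holmBonferroni(p)
    expect_equal(adj, closureAdjust(p))
    # monotone in the raw-p ordering
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p))
  }
})

test_that("the MANOVA step-down descends only below significant gates", {
  set.seed(64)
  n <- 20
  g <- rep(c("control", "tinnitus", "pain"), each = n)
  y <- data.frame(f1 = rnorm(3 * n), f2 = rnorm(3 * n), f3 = rnorm(3 * n),
                  f4 = rnorm(3 * n))
  y$f1[g == "tinnitus"] <- y$f1[g == "tinnitus"] + 2
  fams <- familySpec("all", c("f1", "f2", "f3", "f4"),
                     children = list(familySpec("p1", c("f1", "f2")),
                                     familySpec("p2", c("f3", "f4"))))
  rep1 <- manovaStepdown(y, g, fams)
  expect_true(rep1$multivariate$significant[rep1$multivariate$family == "all"])
  uni <- rep1$univariate
  expect_true(uni$significant[uni$feature == "f1"])
  # pairwise contrasts exist only for surviving features
  expect_true(all(rep1$pairwise$feature %in% uni$feature[uni$significant]))
  expect_equal(sum(rep1$pairwise$feature == "f1"), 3)
  # eta2 within [0, 1]
  expect_true(all(rep1$univariate$eta2 >= 0 & rep1$univariate$eta2 <= 1))
})

test_that("multivariate gates agree with stats::manova and guard family size", {
  set.seed(65)
  n <- 12
  g <- rep(c("a", "b", "c"), each = n)
  Y <- matrix(rnorm(3 * n * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  rep1 <- manovaStepdown(as.data.frame(Y), g, familySpec("uv", c("u", "v")))
  ref <- summary(stats::manova(Y ~ factor(g)), test = "Pillai")$stats
  expect_equal(rep1$multivariate$p, ref[1, "Pr(>F)"])
  expect_equal(rep1$multivariate$statistic, ref[1, "Pillai"])
  big <- as.data.frame(matrix(rnorm(3 * n * 15), ncol = 15))
  expect_error(
    manovaStepdown(big, g, familySpec("big", names(big))), "subfamilies")
})

test_that("null data keep the step-down quiet at roughly the nominal rate", {
  set.seed(66)
  hits <- 0
  for (i in 1:40) {
    y <- data.frame(a = rnorm(30), b = rnorm(30))
    r <- manovaStepdown(y, rep(c("x", "y", "z"), each = 10),
                        familySpec("ab", c("a", "b")))
    if (r$multivariate$significant) hits <- hits + 1
  }
  expect_lte(hits, 7)   # ~5% nominal; binomial slack at 40 runs
})
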