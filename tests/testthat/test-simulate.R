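test_that("group templates encode the planted loop structure", {
  tin <- makeGroupTemplate("tinnitus")
  ed <- templateEdges(tin)
  has <- function(e, s, t) any(e$source == s & e$target == t)
  # parahippocampal-auditory bidirectional, parahippocampal-somatosensory
  # unidirectional (PHC -> SOM only)
  expect_true(has(ed, "lPHC", "lAUD") && has(ed, "lAUD", "lPHC"))
  expect_true(has(ed, "lPHC", "lSOM"))
  expect_false(has(ed, "lSOM", "lPHC"))
  pai <- makeGroupTemplate("pain")
  pe <- templateEdges(pai)
  expect_true(has(pe, "lPHC", "lSOM") && has(pe, "lSOM", "lPHC"))
  expect_true(has(pe, "lPHC", "lAUD"))
  expect_false(has(pe, "lAUD", "lPHC"))
  ctl <- makeGroupTemplate("control")
  expect_equal(nrow(templateEdges(ctl)), 0)
  # patient elevations relative to control
  expect_gt(tin@nodePowers["pgACC", "theta"], ctl@nodePowers["pgACC", "theta"])
  expect_gt(tin@nodePowers["lAUD", "gamma"], ctl@nodePowers["lAUD", "gamma"])
  expect_gt(tin@pacDepth["lSOM"], ctl@pacDepth["lSOM"])
  expect_error(makeGroupTemplate("migraine"), "unknown condition")
  expect_error(makeGroupTemplate("pain", list(bogus = 1)), "override")
})

test_that("unstable coupling configurations are refused with the edge named", {
  tpl <- makeGroupTemplate("tinnitus", list(edgeStrength = 1.3))
  expect_error(simulateSubject(tpl, duration_s = 10), "unstable.*lPHC")
})

test_that("subjects are deterministic under seeds and spectrally in-band", {
  tpl <- makeGroupTemplate("tinnitus")
  a <- simulateSubject(tpl, duration_s = 30, seed = 5)
  b <- simulateSubject(tpl, duration_s = 30, seed = 5)
  d <- simulateSubject(tpl, duration_s = 30, seed = 6)
  expect_identical(a$sources@currents, b$sources@currents)
  expect_false(identical(a$sources@currents, d$sources@currents))
  # bounded variance: no sample beyond 10 stationary SDs
  cur <- a$sources@currents
  for (r in seq_len(dim(cur)[1])) {
    s <- cur[r, , ]
    expect_lt(max(abs(s)), 10 * sd(s))
  }
})

test_that("a planted edge shows as a lagged cross-correlation peak", {
  tpl <- makeGroupTemplate("control")
  tpl@edges <- data.frame(source = "lPHC", target = "lAUD", band = "theta",
                          strength = 0.5, lag = 3L)
  sim <- simulateSubject(tpl, duration_s = 60, seed = 8)
  cur <- sim$sources@currents
  rois <- sim$sources@rois
  pc <- function(r) bandPC1(cur[match(r, rois), , ], 128, c(4, 7.5))
  cc <- ccf(pc("lPHC"), pc("lAUD"), lag.max = 10, plot = FALSE)
  expect_equal(abs(cc$lag[which.max(abs(cc$acf))]), 3)
})

test_that("planted theta-gamma nesting reaches the m/2 mean vector length", {
  tpl <- makeGroupTemplate("control", list(pacDepth = c(
    lAUD = 0.8, rAUD = 0.8, lSOM = 0.8, rSOM = 0.8, lPHC = 0.8, rPHC = 0.8,
    pgACC = 0.8)))
  sim <- simulateSubject(tpl, duration_s = 300, seed = 9, background_amp = 0)
  cur <- sim$sources@currents
  rois <- sim$sources@rois
  th <- bandPC1(cur[match("lAUD", rois), , ], 128, c(4, 7.5))
  # extract the gamma component with a filter wide enough to keep the
  # modulation sidebands (30.5 - 7.5 to 44 + 7.5 Hz), else the measured
  # depth is clipped by the extraction filter rather than the generator
  ga <- bandPC1(cur[match("lAUD", rois), , ], 128, c(20, 60))
  r <- pacMvl(th, ga, 128)
  expect_equal(r$mvl, 0.4, tolerance = 0.10)
})

test_that("cohorts are reproducible, group-balanced and serializable", {
  co <- simulateCohort(2, duration_s = 15, seed = 5)
  co2 <- simulateCohort(2, duration_s = 15, seed = 5)
  expect_identical(co@subjects[[4]]$sources@currents,
                   co2@subjects[[4]]$sources@currents)
  man <- cohortManifest(co)
  expect_equal(unname(table(man$group)["tinnitus"]), 2)
  expect_false(anyDuplicated(man$seed) > 0)
  expect_error(simulateCohort(1), "n_per_group")
  # write/read round-trip with the lead field attached
  sp <- miniSpace(); lf <- miniLeadField()
  col <- simulateCohort(2, duration_s = 15, seed = 5, leadfield = lf,
                        space = sp)
  d <- withr::local_tempdir()
  writeCohort(col, d)
  back <- readCohort(d)
  expect_equal(nrow(back$manifest), 6)
  expect_equal(recordingData(back$subjects[[1]]$recording),
               recordingData(col@subjects[[1]]$recording), tolerance = 1e-9)
  expect_equal(back$subjects[[1]]$truth$condition, "control")
  expect_true(file.exists(file.path(d, "manifest.csv")))
})

test_that("instantaneous mixing produces the declared shapes", {
  x <- scalpMixture(matrix(rnorm(300), 100, 3), matrix(rnorm(6), 2, 3),
                    noise_sd = 0.1)
  expect_equal(dim(x), c(2, 100))
})
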