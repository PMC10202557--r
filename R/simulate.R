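templateROIs <- function() defaultROIs()$roi

#' Build a per-condition group template
#'
#' Encodes the planted effect structure per condition. Both patient templates
#' raise pregenual anterior cingulate theta power, sensory gamma power and
#' theta-gamma modulation depth relative to control. The directed theta
#' couplings differ: the tinnitus template couples parahippocampus and
#' auditory cortex bidirectionally but drives the somatosensory cortex
#' unidirectionally (PHC to SOM only); the pain template is the mirror image
#' (PHC-SOM bidirectional, PHC to AUD only). Both patient templates also
#' couple the two parahippocampi bidirectionally. The control template has no
#' pathological edges and baseline powers and depths.
#'
#' Magnitudes (amplitude ratios 1.8x theta at pgACC, 2x gamma at the six
#' sensory ROIs, modulation depth 0.45 vs 0.10, edge strength 0.5 at lag 3
#' samples, about a quarter-cycle theta delay at 128 Hz) are generator
#' defaults chosen for detectability at 25 subjects per group; see the
#' package vignette.
#'
#' @param condition "control", "tinnitus" or "pain".
#' @param overrides named list overriding declared fields: nodePowers,
#'   pacDepth, edges, edgeStrength, edgeLag.
#' @return A \linkS4class{GroupTemplate}.
#' @examples
#' templateEdges(makeGroupTemplate("tinnitus"))
#' @export
makeGroupTemplate <- function(condition, overrides = list()) {
  if (!condition %in% c("control", "tinnitus", "pain"))
    stop("unknown condition: ", condition)
  bad <- setdiff(names(overrides),
                 c("nodePowers", "pacDepth", "edges", "edgeStrength",
                   "edgeLag"))
  if (length(bad))
    stop("unknown override fields: ", paste(bad, collapse = ", "))
  rois <- templateROIs()
  sensory <- c("lAUD", "rAUD", "lSOM", "rSOM", "lPHC", "rPHC")
  np <- matrix(c(rep(1, length(rois)), rep(0.5, length(rois))),
               ncol = 2, dimnames = list(rois, c("theta", "gamma")))
  pac <- stats::setNames(rep(0.10, length(rois)), rois)
  strength <- if (is.null(overrides$edgeStrength)) 0.5 else overrides$edgeStrength
  lag <- if (is.null(overrides$edgeLag)) 3L else as.integer(overrides$edgeLag)
  edges <- data.frame(source = character(), target = character(),
                      band = character(), strength = numeric(),
                      lag = integer())
  if (condition != "control") {
    np["pgACC", "theta"] <- 1.8
    np[sensory, "gamma"] <- 1.0
    pac[sensory] <- 0.45
    ed <- function(s, t) data.frame(source = s, target = t, band = "theta",
                                    strength = strength, lag = lag)
    edges <- if (condition == "tinnitus") rbind(
      ed("lPHC", "lAUD"), ed("lAUD", "lPHC"),
      ed("rPHC", "rAUD"), ed("rAUD", "rPHC"),
      ed("lPHC", "lSOM"), ed("rPHC", "rSOM"),
      ed("lPHC", "rPHC"), ed("rPHC", "lPHC")
    ) else rbind(
      ed("lPHC", "lSOM"), ed("lSOM", "lPHC"),
      ed("rPHC", "rSOM"), ed("rSOM", "rPHC"),
      ed("lPHC", "lAUD"), ed("rPHC", "rAUD"),
      ed("lPHC", "rPHC"), ed("rPHC", "lPHC")
    )
  }
  if (!is.null(overrides$nodePowers)) {
    o <- overrides$nodePowers
    np[rownames(o), colnames(o)] <- o
  }
  if (!is.null(overrides$pacDepth)) pac[names(overrides$pacDepth)] <- overrides$pacDepth
  if (!is.null(overrides$edges)) edges <- overrides$edges
  new("GroupTemplate", condition = condition, nodePowers = np,
      pacDepth = pac, edges = edges)
}

# Companion spectral radius of the planted coupling operator (theta edges).
templateCouplingRadius <- function(template, rois = templateROIs()) {
  ed <- template@edges
  if (!nrow(ed)) return(0)
  k <- length(rois)
  p <- max(ed$lag)
  A <- array(0, c(k, k, p))
  for (i in seq_len(nrow(ed)))
    A[match(ed$target[i], rois), match(ed$source[i], rois), ed$lag[i]] <-
      A[match(ed$target[i], rois), match(ed$source[i], rois), ed$lag[i]] +
      ed$strength[i]
  mvarCompanionRadius(A)
}

# Apply the lagged coupling recursion x = b + A(L) x by Neumann iteration
# (geometric convergence below the stability boundary).
applyCoupling <- function(b, edges, rois, iter = 14) {
  if (!nrow(edges)) return(b)
  x <- b
  for (it in seq_len(iter)) {
    xn <- b
    for (i in seq_len(nrow(edges))) {
      si <- match(edges$source[i], rois)
      ti <- match(edges$target[i], rois)
      lg <- edges$lag[i]
      n <- nrow(b)
      xn[(lg + 1):n, ti] <- xn[(lg + 1):n, ti] +
        edges$strength[i] * x[1:(n - lg), si]
    }
    x <- xn
  }
  x
}

#' Simulate one subject: source currents and scalp EEG
#'
#' Per-ROI currents are built as a theta narrowband process (white noise
#' filtered into 4-7.5 Hz, zero-phase) plus a gamma narrowband carrier whose
#' envelope is modulated as (1 + m cos theta_phase) / sqrt(1 + m^2/2), plus a
#' small broadband (2-44 Hz) background that keeps autoregressive fits well
#' conditioned. Directed theta edges act as lagged linear influences of the
#' source ROI's theta component on the target's. Each ROI radiates along a
#' fixed random orientation; the scalp EEG is the lead-field projection of
#' all ROI currents (instantaneous mixing: the volume-conduction confound)
#' plus independent sensor noise.
#'
#' @param template a \linkS4class{GroupTemplate}.
#' @param duration_s duration in seconds (>= 10; default 300, a 5-minute
#'   resting recording).
#' @param fs sampling rate in Hz (>= 128).
#' @param leadfield a \linkS4class{LeadField} over \code{space}.
#' @param space the \linkS4class{SolutionSpace} carrying the ROI atlas.
#' @param noise_sd sensor noise SD in microvolts (default 1).
#' @param seed RNG seed.
#' @param source_scale dipole moment scale mapping unit-RMS currents to
#'   scalp microvolts through the lead field (default 2.5e5).
#' @param background_amp RMS of the broadband background component added to
#'   each ROI current.
#' @param n_background number of non-ROI background brain sources projected
#'   to the scalp (whole-brain resting activity; stabilizes the relative
#'   power normalization as in real recordings). Only used with a leadfield.
#' @param background_brain RMS amplitude of each background brain source.
#' @return List with \code{sources} (a \linkS4class{SourceSet}) and
#'   \code{recording} (an \linkS4class{EEGRecording}).
#' @export
simulateSubject <- function(template, duration_s = 300, fs = 128,
                            leadfield = NULL, space = NULL, noise_sd = 1,
                            seed = 1, source_scale = 2.5e5,
                            background_amp = 0.3, n_background = 60,
                            background_brain = 0.7) {
  stopifnot(is(template, "GroupTemplate"))
  if (fs < 128) stop("fs must be >= 128 Hz")
  if (duration_s < 10) stop("duration_s must be >= 10")
  rad <- templateCouplingRadius(template)
  if (rad >= 1) {
    ed <- template@edges
    worst <- ed[which.max(abs(ed$strength)), ]
    stop(sprintf(
      "unstable coupling configuration (spectral radius %.3f); strongest edge %s->%s (strength %.3f, lag %d)",
      rad, worst$source, worst$target, worst$strength, worst$lag))
  }
  rois <- rownames(template@nodePowers)
  n <- round(duration_s * fs)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  thetaB <- defaultBands()$theta; gammaB <- defaultBands()$gamma
  base <- narrowbandNoise(n, fs, thetaB[1], thetaB[2], ncol = length(rois))
  base <- sweep(base, 2, template@nodePowers[, "theta"], "*")
  theta <- applyCoupling(base, template@edges, rois)
  carrier <- narrowbandNoise(n, fs, gammaB[1], gammaB[2], ncol = length(rois))
  backgr <- pinkNoise(n, fs, 2, 44, ncol = length(rois)) * background_amp
  cur <- array(0, c(length(rois), 3, n))
  # fixed radial dipole orientations (anatomically fixed across subjects;
  # the orientation EEG sees best); unknown ROI names fall back to random
  atlas <- defaultROIs()
  dirs <- t(vapply(rois, function(r) {
    k <- match(r, atlas$roi)
    if (!is.na(k)) {
      p <- as.numeric(atlas[k, c("x", "y", "z")])
      p / sqrt(sum(p^2))
    } else {
      d <- stats::rnorm(3)
      d / sqrt(sum(d^2))
    }
  }, numeric(3)))
  for (r in seq_along(rois)) {
    m <- template@pacDepth[rois[r]]
    ph <- Arg(analyticSignal(theta[, r]))
    gam <- template@nodePowers[r, "gamma"] * carrier[, r] *
      (1 + m * cos(ph)) / sqrt(1 + m^2 / 2)
    series <- theta[, r] + gam + backgr[, r]
    cur[r, , ] <- outer(dirs[r, ], series)
  }
  src <- new("SourceSet", rois = rois, currents = cur, fs = fs,
             truth = template)
  rec <- NULL
  if (!is.null(leadfield)) {
    if (is.null(space)) stop("space is required with a leadfield")
    roiTab <- space@roi
    miss <- setdiff(rois, roiTab$roi)
    if (length(miss))
      stop("leadfield/space do not cover ROIs: ", paste(miss, collapse = ", "))
    E <- nrow(leadfield@gain)
    scalp <- matrix(0, E, n)
    for (r in seq_along(rois)) {
      v <- roiTab$voxel[match(rois[r], roiTab$roi)]
      cols <- leadfield@gain[, (3 * v - 2):(3 * v), drop = FALSE]
      series <- colSums(cur[r, , ] * dirs[r, ])   # scalar series along dirs
      scalp <- scalp + (cols %*% dirs[r, ]) %*% matrix(series, nrow = 1)
    }
    if (n_background > 0) {
      pool <- setdiff(seq_len(nrow(space@coords)), roiTab$voxel)
      bgVox <- sample(pool, min(n_background, length(pool)))
      bgDir <- matrix(stats::rnorm(3 * length(bgVox)), length(bgVox), 3)
      bgDir <- bgDir / sqrt(rowSums(bgDir^2))
      bgSer <- pinkNoise(n, fs, 2, 44, ncol = length(bgVox)) *
        background_brain
      topo <- vapply(seq_along(bgVox), function(k)
        as.vector(leadfield@gain[, (3 * bgVox[k] - 2):(3 * bgVox[k]),
                                 drop = FALSE] %*% bgDir[k, ]),
        numeric(E))
      scalp <- scalp + topo %*% t(bgSer)
    }
    scalp <- scalp * source_scale +
      matrix(stats::rnorm(E * n, sd = noise_sd), E, n)
    rec <- eegRecording(scalp, fs = fs, channelLabels = leadfield@montage,
                        map = FALSE)
  }
  list(sources = src, recording = rec)
}

#' Instantaneous mixing of source series (volume-conduction stand-in)
#'
#' Cheap alternative to the full lead-field projection for unit tests of
#' zero-lag-removal properties: sensors are instantaneous linear mixtures of
#' the sources plus independent noise.
#'
#' @param sources samples x k source matrix.
#' @param mixing channels x k mixing matrix.
#' @param noise_sd independent sensor noise SD.
#' @return channels x samples matrix.
#' @export
scalpMixture <- function(sources, mixing, noise_sd = 0) {
  x <- mixing %*% t(as.matrix(sources))
  if (noise_sd > 0) x <- x + matrix(stats::rnorm(length(x), sd = noise_sd),
                                    nrow(x), ncol(x))
  x
}

#' Simulate a three-group cohort
#'
#' Control, tinnitus and pain groups of equal size. Per-subject seeds are
#' derived deterministically from the master seed; inter-subject variability
#' is log-normal multiplicative jitter (default coefficient of variation 0.2)
#' on node powers and edge strengths, and jitter on modulation depths clipped
#' to [0, 1].
#'
#' @param n_per_group subjects per group (>= 2).
#' @param duration_s,fs recording length and rate.
#' @param seed master seed.
#' @param leadfield,space forward model and atlas (see
#'   \code{simulateSubject}); \code{NULL} simulates sources only.
#' @param jitter_cv coefficient of variation of the log-normal jitter.
#' @param noise_sd sensor noise SD in microvolts.
#' @param conditions group labels to simulate.
#' @param ... further arguments passed to \code{simulateSubject}.
#' @return A \linkS4class{Cohort}.
#' @export
simulateCohort <- function(n_per_group, duration_s = 300, fs = 128, seed = 1,
                           leadfield = NULL, space = NULL, jitter_cv = 0.2,
                           noise_sd = 1,
                           conditions = c("control", "tinnitus", "pain"),
                           ...) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  groups <- rep(conditions, each = n_per_group)
  seeds <- deriveSeeds(seed, length(groups))
  sdlog <- sqrt(log(1 + jitter_cv^2))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    tpl <- makeGroupTemplate(groups[i])
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seeds[i] %% .Machine$integer.max)
    jp <- matrix(stats::rlnorm(length(tpl@nodePowers), -sdlog^2 / 2, sdlog),
                 nrow(tpl@nodePowers))
    tpl@nodePowers <- tpl@nodePowers * jp
    tpl@pacDepth[] <- pmin(1, pmax(0, tpl@pacDepth *
      stats::rlnorm(length(tpl@pacDepth), -sdlog^2 / 2, sdlog)))
    if (nrow(tpl@edges)) {
      tpl@edges$strength <- tpl@edges$strength *
        stats::rlnorm(nrow(tpl@edges), -sdlog^2 / 2, sdlog)
      rad <- templateCouplingRadius(tpl)
      if (rad >= 0.9)   # keep jittered couplings clearly inside stability
        tpl@edges$strength <- tpl@edges$strength * (0.9 / rad)^3
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    sim <- simulateSubject(tpl, duration_s = duration_s, fs = fs,
                           leadfield = leadfield, space = space,
                           noise_sd = noise_sd, seed = seeds[i], ...)
    subjects[[i]] <- list(id = sprintf("S%03d", i), group = groups[i],
                          recording = sim$recording, sources = sim$sources,
                          seed = seeds[i])
  }
  manifest <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "id"),
    group = groups,
    seed = seeds)
  new("Cohort", subjects = subjects, seed = seed, manifest = manifest)
}

#' Write a cohort to a directory
#'
#' One recording file per subject (CSV or EDF) plus a JSON sidecar with the
#' jittered ground-truth template and seed, and a cohort manifest CSV
#' (subject_id, group, seed).
#'
#' @param cohort a \linkS4class{Cohort} simulated with a lead field.
#' @param dir output directory (created if needed).
#' @param format "csv" or "edf".
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort@subjects) {
    if (is.null(s$recording))
      stop("cohort was simulated without a lead field; no recordings to write")
    writeRecording(s$recording, file.path(dir, paste0(s$id, ".", format)),
                   format)
    tpl <- s$sources@truth
    sidecar <- list(
      subject_id = s$id, group = s$group, seed = s$seed,
      condition = tpl@condition,
      node_powers = as.data.frame(tpl@nodePowers),
      rois = rownames(tpl@nodePowers),
      pac_depth = as.list(tpl@pacDepth),
      edges = tpl@edges)
    jsonlite::write_json(sidecar, file.path(dir, paste0(s$id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(cohort@manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by \code{writeCohort}
#'
#' @param dir cohort directory.
#' @return List with \code{manifest} and \code{subjects} (each with id,
#'   group, seed, recording, truth).
#' @export
readCohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$subject_id[i]
    fn <- list.files(dir, pattern = paste0("^", id, "\\.(csv|edf)$"),
                     full.names = TRUE)[1]
    truth <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                                 simplifyVector = TRUE)
    list(id = id, group = man$group[i], seed = man$seed[i],
         recording = readRecording(fn), truth = truth)
  })
  list(manifest = man, subjects = subjects)
}
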