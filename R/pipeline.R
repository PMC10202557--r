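#' Default pipeline configuration
#'
#' Flat key-tree configuration covering every stage. Every random stage has
#' an explicit seed derived from the master \code{seed}. The configuration
#' used for a run is embedded (as YAML, with its MD5 hash) in all outputs.
#'
#' @param ... overrides, as \code{name = value} pairs at the top level or
#'   nested lists (e.g. \code{simulate = list(n_per_group = 25)}).
#' @return Named list with the merged configuration.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1,
    grid = "mini",
    input_dir = NULL,
    out_dir = NULL,
    simulate = list(n_per_group = 5, duration_s = 120, fs = 128,
                    jitter_cv = 0.2, noise_sd = 1),
    preprocess = list(lo = 2, hi = 44, fs_target = 128),
    epochs = list(epoch_len_s = 4, taper = "hanning", amp_reject_uV = 250),
    inverse = list(alpha = NULL),
    bands_of_interest = c("theta", "gamma"),
    lpc = list(form = "phase", significance = FALSE, n_shuffles = 200),
    gc = list(order = 12, band = "theta", crosstalk_correction = TRUE,
              leakage_correction = FALSE),
    pac = list(n_surrogates = 200),
    inference = list(n_perm = 1000, alpha = 0.05, z_thresh = 1.96)
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  mergeTree <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- mergeTree(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  mergeTree(cfg, overrides)
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# Nested family tree for the 22-link GC roster, collapsing families that the
# per-group sample size cannot support into their subfamilies.
gcFamilies <- function(n_min) {
  roster <- gcLinkRoster()
  linkName <- function(s, t) paste0(s, "_to_", t)
  pairFam <- function(a, b, nm)
    familySpec(nm, c(linkName(a, b), linkName(b, a)))
  hub <- c("lAUD", "rAUD", "lSOM", "rSOM", "lPHC", "rPHC")
  pg <- lapply(hub, function(h) pairFam("pgACC", h, paste0("pgACC_", h)))
  sens <- list(pairFam("lAUD", "lPHC", "lAUD_lPHC"),
               pairFam("rAUD", "rPHC", "rAUD_rPHC"),
               pairFam("lSOM", "lPHC", "lSOM_lPHC"),
               pairFam("rSOM", "rPHC", "rSOM_rPHC"))
  fams <- list(
    familySpec("pgACC_links",
               unlist(lapply(pg, `[[`, "features")), children = pg),
    familySpec("sensory_PHC_links",
               unlist(lapply(sens, `[[`, "features")), children = sens),
    familySpec("interhemispheric_PHC",
               c(linkName("lPHC", "rPHC"), linkName("rPHC", "lPHC")))
  )
  # a family's multivariate test needs more subjects per group than features;
  # oversized leaves fall back to per-feature (univariate) families
  flatten <- function(f) {
    if (length(f$features) < n_min) return(list(f))
    if (!is.null(f$children)) return(do.call(c, lapply(f$children, flatten)))
    lapply(f$features, function(ft)
      familySpec(paste0(f$name, "_", ft), ft))
  }
  do.call(c, lapply(fams, flatten))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> preprocess -> common average reference ->
#' sLORETA inversion -> ROI log relative power -> lagged phase coherence ->
#' theta Granger causality -> theta-gamma PAC -> group inference, and
#' (optionally) writes per-stage CSV tables, a JSON summary and a run log.
#'
#' @param config configuration from \code{pipelineConfig()}.
#' @return List of class \code{"pipelineResult"}: config, hash, manifest,
#'   power (subjects x ROI.band), lpcTheta, gcWide (subjects x 22 links),
#'   pac (subjects x ROIs), tables (long per-stage data.frames), and
#'   \code{stats} (maxstat, contrasts, conjunction, step-down reports).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- pipelineConfig(config)
  hash <- configHash(cfg)
  t0 <- Sys.time()
  logLines <- c(sprintf("oscloop pipeline run %s", format(t0)),
                sprintf("config hash: %s", hash),
                sprintf("R %s, oscloop %s", getRversion(),
                        as.character(utils::packageVersion("oscloop"))))
  say <- function(fmt, ...) {
    logLines <<- c(logLines, sprintf(fmt, ...))
  }
  space <- solutionSpace(cfg$grid)
  montage <- standard1020Positions()
  lf <- buildLeadField(montage, space)
  op <- sloretaOperator(lf, alpha = cfg$inverse$alpha)
  say("grid %s: %d voxels; sLORETA alpha %.4g", cfg$grid,
      nrow(voxelCoords(space)), op@alpha)

  stageFail <- function(stage, id, e)
    stop(sprintf("stage '%s' failed for subject %s: %s", stage, id,
                 conditionMessage(e)), call. = FALSE)

  if (!is.null(cfg$input_dir)) {
    raw <- readCohort(cfg$input_dir)
    subjects <- lapply(raw$subjects, function(s)
      list(id = s$id, group = s$group, recording = s$recording))
    manifest <- raw$manifest
    say("read %d subjects from %s", length(subjects), cfg$input_dir)
  } else {
    co <- simulateCohort(cfg$simulate$n_per_group,
                         duration_s = cfg$simulate$duration_s,
                         fs = cfg$simulate$fs, seed = cfg$seed,
                         leadfield = lf, space = space,
                         jitter_cv = cfg$simulate$jitter_cv,
                         noise_sd = cfg$simulate$noise_sd)
    subjects <- cohortSubjects(co)
    manifest <- cohortManifest(co)
    say("simulated %d subjects (%d per group), %g s at %g Hz",
        length(subjects), cfg$simulate$n_per_group, cfg$simulate$duration_s,
        cfg$simulate$fs)
  }

  bands <- defaultBands()
  boi <- bands[cfg$bands_of_interest]
  nSub <- length(subjects)
  power <- NULL; lpcRows <- list(); gcRows <- list(); pacRows <- list()
  for (i in seq_len(nSub)) {
    s <- subjects[[i]]
    rec <- tryCatch(
      preprocessRecording(s$recording, cfg$preprocess$lo, cfg$preprocess$hi,
                          cfg$preprocess$fs_target),
      error = function(e) stageFail("preprocess", s$id, e))
    rec <- tryCatch(commonAverageReference(rec),
                    error = function(e) stageFail("reference", s$id, e))
    cd <- tryCatch(applyInverse(op, rec),
                   error = function(e) stageFail("inverse", s$id, e))
    pw <- tryCatch(roiBandPower(cd, space, boi),
                   error = function(e) stageFail("roi_power", s$id, e))
    if (is.null(power))
      power <- matrix(NA_real_, nSub, length(pw),
                      dimnames = list(manifest$subject_id,
                                      paste(rep(rownames(pw), ncol(pw)),
                                            rep(colnames(pw), each = nrow(pw)),
                                            sep = ".")))
    power[i, ] <- as.vector(pw)
    roiXYZ <- roiTimeSeries(cd, space)
    roiPC <- t(vapply(roiXYZ, function(m) bandPC1(m, samplingRate(cd)),
                      numeric(ncol(cd@j))))
    cs <- tryCatch(
      epochCrossSpectra(roiPC, epoch_len_s = cfg$epochs$epoch_len_s,
                        bands = bands, taper = cfg$epochs$taper,
                        amp_reject_uV = Inf, fs = samplingRate(cd)),
      error = function(e) stageFail("cross_spectra", s$id, e))
    lpc <- tryCatch(
      lpcTable(cs, form = cfg$lpc$form,
               significance = cfg$lpc$significance,
               n_shuffles = cfg$lpc$n_shuffles, seed = cfg$seed + i),
      error = function(e) stageFail("lpc", s$id, e))
    lpc$subject_id <- s$id
    lpcRows[[i]] <- lpc
    gcSeries <- if (isTRUE(cfg$gc$crosstalk_correction)) {
      est <- crosstalkCorrectedSeries(op, lf, space, rec)
      stats::setNames(lapply(seq_len(nrow(est)), function(r) est[r, ]),
                      rownames(est))
    } else {
      stats::setNames(lapply(seq_len(nrow(roiPC)), function(r) roiPC[r, ]),
                      rownames(roiPC))
    }
    gc <- tryCatch(
      gcTable(gcSeries,
              fs = samplingRate(cd), band = bands[[cfg$gc$band]],
              order = cfg$gc$order,
              leakage_correction = isTRUE(cfg$gc$leakage_correction)),
      error = function(e) stageFail("granger", s$id, e))
    gc$subject_id <- s$id
    gcRows[[i]] <- gc
    pac <- tryCatch(
      pacTable(roiXYZ[setdiff(names(roiXYZ), "pgACC")],
               fs = samplingRate(cd),
               n_surrogates = cfg$pac$n_surrogates, seed = cfg$seed + i),
      error = function(e) stageFail("pac", s$id, e))
    pac$subject_id <- s$id
    pacRows[[i]] <- pac
  }
  say("per-subject feature extraction done (%.1f s)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  groups <- manifest$group
  lpcLong <- do.call(rbind, lpcRows)
  gcLong <- do.call(rbind, gcRows)
  pacLong <- do.call(rbind, pacRows)
  links <- unique(paste0(gcLong$source_roi, "_to_", gcLong$target_roi))
  gcWide <- matrix(NA_real_, nSub, length(links),
                   dimnames = list(manifest$subject_id, links))
  for (k in seq_len(nrow(gcLong)))
    gcWide[gcLong$subject_id[k],
           paste0(gcLong$source_roi[k], "_to_", gcLong$target_roi[k])] <-
      gcLong$gc[k]
  pacWide <- matrix(NA_real_, nSub, length(unique(pacLong$roi)),
                    dimnames = list(manifest$subject_id, unique(pacLong$roi)))
  for (k in seq_len(nrow(pacLong)))
    pacWide[pacLong$subject_id[k], pacLong$roi[k]] <- pacLong$mvl[k]
  thetaLpc <- lpcLong[lpcLong$band == "theta", ]
  lpcPairs <- unique(paste(thetaLpc$roi_i, thetaLpc$roi_j, sep = "~"))
  lpcWide <- matrix(NA_real_, nSub, length(lpcPairs),
                    dimnames = list(manifest$subject_id, lpcPairs))
  for (k in seq_len(nrow(thetaLpc)))
    lpcWide[thetaLpc$subject_id[k],
            paste(thetaLpc$roi_i[k], thetaLpc$roi_j[k], sep = "~")] <-
      thetaLpc$lpc[k]

  inf <- cfg$inference
  maxstat <- permutationMaxstat(power, groups, n_perm = inf$n_perm,
                                alpha = inf$alpha, seed = cfg$seed)
  contrasts <- list()
  for (grp in setdiff(unique(groups), "control")) {
    sel <- groups %in% c("control", grp)
    contrasts[[grp]] <- contrastZ(
      power[sel, , drop = FALSE],
      factor(groups[sel], levels = c("control", grp)),
      n_perm = inf$n_perm, seed = cfg$seed + 17)
  }
  conj <- if (length(contrasts) == 2)
    conjunctionMin(contrasts[[1]], contrasts[[2]], inf$z_thresh) else NULL
  nMin <- min(table(groups))
  gcReport <- manovaStepdown(as.data.frame(gcWide), groups,
                             gcFamilies(nMin), alpha = inf$alpha)
  pacFams <- if (nMin > ncol(pacWide)) {
    familySpec("pac_sensory", colnames(pacWide))
  } else {
    lapply(colnames(pacWide), function(f) familySpec(paste0("pac_", f), f))
  }
  pacReport <- manovaStepdown(as.data.frame(pacWide), groups, pacFams,
                              alpha = inf$alpha)
  lpcMaxstat <- permutationMaxstat(lpcWide, groups, n_perm = inf$n_perm,
                                   alpha = inf$alpha, seed = cfg$seed + 31)
  say("group inference done (%.1f s total)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- structure(list(
    config = cfg, hash = hash, manifest = manifest,
    power = power, lpcTheta = lpcWide, gcWide = gcWide, pac = pacWide,
    tables = list(lpc = lpcLong, gc = gcLong, pac = pacLong),
    stats = list(power_maxstat = maxstat, power_contrasts = contrasts,
                 power_conjunction = conj, gc_stepdown = gcReport,
                 pac_stepdown = pacReport, lpc_maxstat = lpcMaxstat),
    log = logLines), class = "pipelineResult")
  if (!is.null(cfg$out_dir)) writeTables(res, cfg$out_dir)
  res
}

#' @export
print.pipelineResult <- function(x, ...) {
  cat(sprintf("oscloop pipeline result: %d subjects, grid '%s', hash %s\n",
              nrow(x$manifest), x$config$grid, substr(x$hash, 1, 8)))
  sig <- names(which(x$stats$power_maxstat$pCorr < x$config$inference$alpha))
  cat("power features significant after max-statistic correction:\n  ",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes the per-stage long tables, the wide feature matrices, the manifest,
#' a JSON summary of the group statistics and the run log to a directory.
#' Every CSV carries a header comment with the configuration hash; floats are
#' written at 6 significant digits; column order is stable.
#'
#' @param results a \code{pipelineResult}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
writeTables <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  hash <- results$hash
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# oscloop config %s", hash), con)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, con, row.names = FALSE)
  }
  wide2df <- function(m) {
    if (is.null(m)) return(data.frame())
    data.frame(subject_id = rownames(m), as.data.frame(m),
               check.names = FALSE)
  }
  wcsv(results$manifest, "manifest.csv")
  wcsv(results$tables$lpc, "lpc.csv")
  wcsv(results$tables$gc, "gc.csv")
  wcsv(results$tables$pac, "pac.csv")
  wcsv(wide2df(results$power), "roi_power.csv")
  st <- results$stats
  if (!is.null(st$gc_stepdown)) {
    wcsv(st$gc_stepdown$multivariate, "gc_multivariate.csv")
    wcsv(st$gc_stepdown$univariate, "gc_univariate.csv")
    wcsv(st$gc_stepdown$pairwise, "gc_pairwise.csv")
  }
  summary <- list(
    config = results$config, config_hash = hash,
    power_maxstat = list(
      threshold = st$power_maxstat$threshold,
      p_corr = as.list(stats::setNames(st$power_maxstat$pCorr,
                                       colnames(results$power)))),
    power_conjunction = if (!is.null(st$power_conjunction)) list(
      min_z = as.list(stats::setNames(st$power_conjunction$minZ,
                                      colnames(results$power))),
      z_thresh = st$power_conjunction$z_thresh))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  yaml::write_yaml(results$config, file.path(out_dir, "config.yaml"))
  writeLines(results$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
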