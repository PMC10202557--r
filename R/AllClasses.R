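#' @import methods
NULL

#' Multichannel scalp EEG recording
#'
#' Container for a channels-by-samples EEG data matrix together with its
#' sampling rate, channel labels (10-20 names) and referencing state.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique channel names.
#' @slot reference either \code{"original"} or \code{"common_average"}.
#'
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    reference = "character"
  ),
  prototype(reference = "original")
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "nrow(data) must equal length(channelLabels)")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!object@reference %in% c("original", "common_average"))
    msg <- c(msg, "reference must be 'original' or 'common_average'")
  if (object@reference == "common_average" && ncol(object@data) > 0) {
    mu <- max(abs(colMeans(object@data)))
    sc <- max(1, max(abs(object@data)))
    if (mu > 1e-6 * sc)
      msg <- c(msg, "common_average recording has non-zero per-sample channel means")
  }
  if (length(msg)) msg else TRUE
})

#' Per-band averaged Fourier cross-spectral matrices
#'
#' Holds, for each frequency band, the complex cross-spectral matrix averaged
#' over epochs and over the Fourier bins inside the band, plus the per-epoch
#' Fourier coefficients retained for phase-synchronization variants and
#' epoch-shuffling surrogates.
#'
#' @slot S named list, one channels-x-channels complex Hermitian matrix per band.
#' @slot coef named list, one channels x bins x epochs complex array per band
#'   (raw Fourier coefficients of tapered epochs).
#' @slot bands named list of c(lo, hi) band edges in Hz.
#' @slot nEpochs number of epochs retained.
#' @slot epochLen epoch length in seconds.
#' @slot taper taper name.
#' @slot channelLabels channel names, in matrix order.
#' @slot fs sampling rate in Hz.
#'
#' @export
setClass("BandCrossSpectra",
  representation(
    S = "list", coef = "list", bands = "list",
    nEpochs = "numeric", epochLen = "numeric", taper = "character",
    channelLabels = "character", fs = "numeric"
  )
)

setValidity("BandCrossSpectra", function(object) {
  msg <- character()
  if (object@nEpochs < 2) msg <- c(msg, "need at least 2 epochs")
  for (b in names(object@S)) {
    S <- object@S[[b]]
    if (max(abs(S - Conj(t(S)))) > 1e-8 * max(1, max(abs(S))))
      msg <- c(msg, sprintf("cross-spectrum for band '%s' is not Hermitian", b))
    if (any(Re(diag(S)) < -1e-12) || max(abs(Im(diag(S)))) > 1e-8 * max(1, max(abs(S))))
      msg <- c(msg, sprintf("band '%s' auto-spectra must be real and non-negative", b))
  }
  if (length(msg)) msg else TRUE
})

#' Voxel grid and region-of-interest atlas
#'
#' A spherical-shell solution space: voxel centres in head-frame millimetres
#' (origin at the sphere centre) plus named single-voxel regions of interest.
#'
#' @slot coords numeric matrix, voxels x 3, mm.
#' @slot voxelSize lattice spacing in mm.
#' @slot roi data.frame with columns roi, x, y, z (requested coordinates) and
#'   voxel (index of the snapped grid voxel).
#' @slot preset name of the grid preset the space was built from.
#'
#' @export
setClass("SolutionSpace",
  representation(coords = "matrix", voxelSize = "numeric",
                 roi = "data.frame", preset = "character")
)

setValidity("SolutionSpace", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be voxels x 3")
  if (nrow(object@roi)) {
    if (!all(c("roi", "x", "y", "z", "voxel") %in% names(object@roi)))
      msg <- c(msg, "roi table needs columns roi, x, y, z, voxel")
    else {
      if (any(object@roi$voxel < 1 | object@roi$voxel > nrow(object@coords)))
        msg <- c(msg, "ROI voxel indices outside the grid")
      if (anyDuplicated(object@roi$voxel))
        msg <- c(msg, "two ROIs snapped to the same voxel; use a finer grid")
      if (anyDuplicated(object@roi$roi))
        msg <- c(msg, "ROI names must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Electrode-to-source gain matrix
#'
#' Lead field mapping unit dipole moments at grid voxels (3 orthogonal
#' orientations each) to scalp electrode potentials.
#'
#' @slot gain numeric matrix, electrodes x (3 * voxels); columns are grouped
#'   per voxel as (x, y, z) moments.
#' @slot model "three_shell_sphere" or "synthetic".
#' @slot montage electrode labels, in row order.
#' @slot positions electrodes x 3 matrix of electrode positions (mm).
#'
#' @export
setClass("LeadField",
  representation(gain = "matrix", model = "character",
                 montage = "character", positions = "matrix")
)

setValidity("LeadField", function(object) {
  msg <- character()
  if (!all(is.finite(object@gain))) msg <- c(msg, "gain must be finite")
  if (nrow(object@gain) != length(object@montage))
    msg <- c(msg, "gain rows must match montage")
  if (ncol(object@gain) %% 3L != 0L)
    msg <- c(msg, "gain columns must come in triplets")
  if (!object@model %in% c("three_shell_sphere", "synthetic"))
    msg <- c(msg, "unknown lead-field model")
  if (length(msg)) msg else TRUE
})

#' sLORETA inverse operator
#'
#' Minimum-norm inverse with sLORETA standardization: the pseudoinverse-based
#' operator T plus the 3x3 diagonal blocks of the resolution matrix T L used
#' to standardize voxel current estimates.
#'
#' @slot T numeric matrix, (3 * voxels) x electrodes.
#' @slot alpha regularization parameter (units of the eigenvalues of L L^t).
#' @slot resBlocks 3 x 3 x voxels array of resolution-matrix diagonal blocks.
#' @slot blockInv 3 x 3 x voxels array of their (pseudo)inverses.
#' @slot montage electrode labels expected by the operator.
#'
#' @export
setClass("InverseOperator",
  representation(T = "matrix", alpha = "numeric",
                 resBlocks = "array", blockInv = "array", montage = "character")
)

#' Source-space current density
#'
#' Estimated 3-component dipole moment per voxel per sample, stored as a
#' (3 * voxels) x samples matrix with rows grouped per voxel.
#'
#' @slot j numeric matrix, (3 * voxels) x samples.
#' @slot fs sampling rate in Hz.
#' @slot nVoxels number of voxels.
#'
#' @export
setClass("CurrentDensity",
  representation(j = "matrix", fs = "numeric", nVoxels = "numeric")
)

setValidity("CurrentDensity", function(object) {
  msg <- character()
  if (nrow(object@j) != 3L * object@nVoxels)
    msg <- c(msg, "j must have 3 rows per voxel")
  if (!all(is.finite(object@j))) msg <- c(msg, "current density must be finite")
  if (length(msg)) msg else TRUE
})

#' Group template for the synthetic-cohort generator
#'
#' Encodes the per-condition ground truth: per-ROI per-band oscillation
#' amplitudes, per-ROI theta-gamma modulation depths, and the list of planted
#' directed band-limited couplings.
#'
#' @slot condition "control", "tinnitus" or "pain".
#' @slot nodePowers numeric matrix, ROIs x bands (RMS amplitude, arbitrary units).
#' @slot pacDepth named numeric vector, modulation depth m in [0, 1] per ROI.
#' @slot edges data.frame with columns source, target, band, strength, lag
#'   (lag in samples, >= 1).
#'
#' @export
setClass("GroupTemplate",
  representation(condition = "character", nodePowers = "matrix",
                 pacDepth = "numeric", edges = "data.frame")
)

setValidity("GroupTemplate", function(object) {
  msg <- character()
  if (!object@condition %in% c("control", "tinnitus", "pain"))
    msg <- c(msg, "condition must be control, tinnitus or pain")
  if (any(object@pacDepth < 0 | object@pacDepth > 1))
    msg <- c(msg, "pac depths must lie in [0, 1]")
  rois <- rownames(object@nodePowers)
  if (!identical(sort(names(object@pacDepth)), sort(rois)))
    msg <- c(msg, "pacDepth must be named by the template ROIs")
  if (nrow(object@edges)) {
    if (!all(c(object@edges$source, object@edges$target) %in% rois))
      msg <- c(msg, "edges reference ROIs absent from the template atlas")
    if (any(object@edges$lag < 1))
      msg <- c(msg, "edge lags must be >= 1 sample")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth source currents for one simulated subject
#'
#' @slot rois ROI names, in array order.
#' @slot currents numeric array, ROIs x 3 x samples (3-component current).
#' @slot fs sampling rate in Hz.
#' @slot truth the GroupTemplate (with subject jitter applied) that generated it.
#'
#' @export
setClass("SourceSet",
  representation(rois = "character", currents = "array",
                 fs = "numeric", truth = "GroupTemplate")
)

setValidity("SourceSet", function(object) {
  msg <- character()
  d <- dim(object@currents)
  if (length(d) != 3L || d[1] != length(object@rois) || d[2] != 3L)
    msg <- c(msg, "currents must be ROIs x 3 x samples")
  if (!all(is.finite(object@currents))) msg <- c(msg, "currents must be finite")
  if (length(msg)) msg else TRUE
})

#' Simulated cohort with ground truth
#'
#' @slot subjects list; each element is a list with fields id, group,
#'   recording (EEGRecording), sources (SourceSet), seed.
#' @slot seed master seed the cohort was generated from.
#' @slot manifest data.frame (subject_id, group, seed).
#'
#' @export
setClass("Cohort",
  representation(subjects = "list", seed = "numeric", manifest = "data.frame")
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%s reference)\n",
              nrow(object@data), ncol(object@data), object@fs, object@reference))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
})

setMethod("show", "BandCrossSpectra", function(object) {
  cat(sprintf("BandCrossSpectra: %d channels, %d epochs of %gs (%s taper)\n",
              length(object@channelLabels), object@nEpochs, object@epochLen,
              object@taper))
  cat("  bands:", paste(names(object@bands), collapse = " "), "\n")
})

setMethod("show", "SolutionSpace", function(object) {
  cat(sprintf("SolutionSpace '%s': %d voxels, %g mm spacing, %d ROIs\n",
              object@preset, nrow(object@coords), object@voxelSize,
              nrow(object@roi)))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField (%s): %d electrodes x %d voxels\n",
              object@model, nrow(object@gain), ncol(object@gain) / 3L))
})

setMethod("show", "InverseOperator", function(object) {
  cat(sprintf("sLORETA InverseOperator: %d voxels, %d electrodes, alpha = %g\n",
              nrow(object@T) / 3L, ncol(object@T), object@alpha))
})

setMethod("show", "CurrentDensity", function(object) {
  cat(sprintf("CurrentDensity: %d voxels x 3 x %d samples @ %g Hz\n",
              object@nVoxels, ncol(object@j), object@fs))
})

setMethod("show", "GroupTemplate", function(object) {
  cat(sprintf("GroupTemplate '%s': %d ROIs, %d planted edges\n",
              object@condition, nrow(object@nodePowers), nrow(object@edges)))
})

setMethod("show", "SourceSet", function(object) {
  cat(sprintf("SourceSet: %d ROIs x 3 x %d samples @ %g Hz (condition %s)\n",
              length(object@rois), dim(object@currents)[3], object@fs,
              object@truth@condition))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(vapply(object@subjects, `[[`, "", "group"))
  cat(sprintf("Cohort: %d subjects (seed %d): %s\n", length(object@subjects),
              object@seed,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for oscloop objects
#'
#' Small generic accessors used throughout the package instead of direct slot
#' access.
#'
#' @param object an oscloop S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "CurrentDensity", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SourceSet", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "LeadField", function(object) object@montage)

#' @rdname accessors
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setMethod("recordingData", "EEGRecording", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))
#' @rdname accessors
#' @export
setMethod("voxelCoords", "SolutionSpace", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("roiTable", function(object) standardGeneric("roiTable"))
#' @rdname accessors
#' @export
setMethod("roiTable", "SolutionSpace", function(object) object@roi)

#' @rdname accessors
#' @export
setGeneric("gainMatrix", function(object) standardGeneric("gainMatrix"))
#' @rdname accessors
#' @export
setMethod("gainMatrix", "LeadField", function(object) object@gain)

#' @rdname accessors
#' @export
setGeneric("crossSpectrum", function(object, band) standardGeneric("crossSpectrum"))
#' @rdname accessors
#' @param band band name.
#' @export
setMethod("crossSpectrum", "BandCrossSpectra", function(object, band) {
  if (!band %in% names(object@S)) stop("unknown band: ", band)
  object@S[[band]]
})

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SourceSet", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("cohortManifest", function(object) standardGeneric("cohortManifest"))
#' @rdname accessors
#' @export
setMethod("cohortManifest", "Cohort", function(object) object@manifest)

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))
#' @rdname accessors
#' @export
setMethod("cohortSubjects", "Cohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setGeneric("templateEdges", function(object) standardGeneric("templateEdges"))
#' @rdname accessors
#' @export
setMethod("templateEdges", "GroupTemplate", function(object) object@edges)
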