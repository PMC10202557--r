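#' sLORETA inverse operator
#'
#' Builds the standardized minimum-norm inverse: with average-reference
#' centering H = I - 11'/E and row-centred lead field L, the minimum-norm
#' operator is T = L' (L L' + alpha H)^+ and voxel estimates are standardized
#' by the 3x3 diagonal blocks of the resolution matrix T L. Standardized power
#' at voxel l for a measurement phi is j_l' [TL]_ll^-1 j_l with j = T phi.
#' With noise-free data from a single point source this standardized power is
#' maximal exactly at the source voxel, for any alpha >= 0 (the defining
#' zero-localization-error property).
#'
#' @param leadfield a \linkS4class{LeadField}.
#' @param alpha regularization parameter; \code{NULL} (default) uses 1e-2
#'   times the mean eigenvalue of L L'; 0 requests the pure pseudoinverse.
#' @return An \linkS4class{InverseOperator}.
#' @export
sloretaOperator <- function(leadfield, alpha = NULL) {
  stopifnot(is(leadfield, "LeadField"))
  L <- leadfield@gain
  E <- nrow(L)
  H <- diag(E) - matrix(1 / E, E, E)
  L <- H %*% L                          # average-reference the forward model
  M <- tcrossprod(L)
  if (is.null(alpha)) alpha <- 1e-2 * mean(diag(M))
  if (alpha < 0) stop("alpha must be >= 0")
  K <- symPinv(M + alpha * H)
  Tmat <- crossprod(L, K)               # (3N) x E
  nV <- ncol(L) / 3L
  resBlocks <- array(0, c(3, 3, nV))
  blockInv <- array(0, c(3, 3, nV))
  for (v in seq_len(nV)) {
    idx <- (3 * v - 2):(3 * v)
    B <- Tmat[idx, , drop = FALSE] %*% L[, idx, drop = FALSE]
    B <- (B + t(B)) / 2
    resBlocks[, , v] <- B
    blockInv[, , v] <- symPinv(B)
  }
  new("InverseOperator", T = Tmat, alpha = alpha,
      resBlocks = resBlocks, blockInv = blockInv,
      montage = leadfield@montage)
}

#' Apply an inverse operator to a recording
#'
#' Computes the current-density estimate j(t) = T phi(t) for every sample.
#'
#' @param operator an \linkS4class{InverseOperator}.
#' @param recording a common-average referenced \linkS4class{EEGRecording}
#'   whose montage matches the operator, or a plain electrodes x samples
#'   matrix.
#' @return A \linkS4class{CurrentDensity}.
#' @export
applyInverse <- function(operator, recording) {
  stopifnot(is(operator, "InverseOperator"))
  if (is(recording, "EEGRecording")) {
    if (!identical(recording@channelLabels, operator@montage)) {
      missing <- setdiff(operator@montage, recording@channelLabels)
      extra <- setdiff(recording@channelLabels, operator@montage)
      stop("montage mismatch; missing: ",
           paste(missing, collapse = ", "), "; unexpected: ",
           paste(extra, collapse = ", "))
    }
    if (recording@reference != "common_average")
      stop("apply commonAverageReference() before inversion")
    phi <- recording@data
    fs <- recording@fs
  } else {
    phi <- as.matrix(recording)
    fs <- NA_real_
  }
  j <- operator@T %*% phi
  new("CurrentDensity", j = j, fs = fs, nVoxels = nrow(operator@T) / 3L)
}

#' Standardized voxel power of a current-density estimate
#'
#' Per voxel and sample (or averaged over samples), the sLORETA standardized
#' power j_l' [TL]_ll^-1 j_l.
#'
#' @param operator the \linkS4class{InverseOperator} used for the estimate.
#' @param cd a \linkS4class{CurrentDensity} (or a (3N) x samples matrix).
#' @param average average over samples (default TRUE).
#' @return If \code{average}, a vector of voxel powers; else voxels x samples.
#' @export
standardizedPower <- function(operator, cd, average = TRUE) {
  j <- if (is(cd, "CurrentDensity")) cd@j else as.matrix(cd)
  nV <- nrow(j) / 3L
  out <- matrix(0, nV, ncol(j))
  for (v in seq_len(nV)) {
    idx <- (3 * v - 2):(3 * v)
    out[v, ] <- colSums(j[idx, , drop = FALSE] *
                          (operator@blockInv[, , v] %*% j[idx, , drop = FALSE]))
  }
  if (average) rowMeans(out) else out
}

#' Log-transformed relative ROI band power
#'
#' For each band: band-pass the 3-component voxel currents (same zero-phase
#' filters as preprocessing), form voxel power as the squared current
#' magnitude summed over the three orientations, normalize the powers across
#' all grid voxels to sum to 1 at every time step, average the fractions over
#' time, and take the natural log. The ROI value is the value at the ROI's
#' single voxel, i.e. the log-transformed fraction of overall power.
#'
#' @param cd a \linkS4class{CurrentDensity}.
#' @param space the \linkS4class{SolutionSpace} with ROI definitions.
#' @param bands named list of band edges (default theta and gamma).
#' @return Matrix ROIs x bands of log relative power.
#' @export
roiBandPower <- function(cd, space, bands = defaultBands()[c("theta", "gamma")]) {
  stopifnot(is(cd, "CurrentDensity"), is(space, "SolutionSpace"))
  validateBands(bands)
  if (!nrow(space@roi)) stop("solution space has no ROIs")
  if (all(cd@j == 0)) stop("silent recording: relative log power undefined")
  nV <- cd@nVoxels
  out <- matrix(NA_real_, nrow(space@roi), length(bands),
                dimnames = list(space@roi$roi, names(bands)))
  n <- ncol(cd@j)
  fa <- abs(fftFreqs(n, cd@fs))
  X <- stats::mvfft(t(cd@j))            # one forward transform, all components
  bn <- names(bands)
  # zero-phase responses are real and symmetric, so two bands can share one
  # inverse transform: ifft(X * (H1 + i H2)) = y1 + i y2 for real input.
  # The inverse transform runs over voxel chunks to keep temporaries small.
  chunk <- 100L
  k <- 1
  while (k <= length(bn)) {
    two <- k + 1 <= length(bn)
    H1 <- raisedCosineResponse(fa, bands[[bn[k]]][1], bands[[bn[k]]][2], 0.5)
    H <- if (two) {
      H1 + 1i * raisedCosineResponse(fa, bands[[bn[k + 1]]][1],
                                     bands[[bn[k + 1]]][2], 0.5)
    } else H1 + 0i
    sum1 <- matrix(0, n, nV)            # per-band voxel power over time
    sum2 <- if (two) matrix(0, n, nV)
    for (v0 in seq(1, nV, by = chunk)) {
      v1 <- min(v0 + chunk - 1L, nV)
      cols <- (3 * v0 - 2):(3 * v1)
      Y <- stats::mvfft(X[, cols, drop = FALSE] * H, inverse = TRUE) / n
      dim3 <- function(jf) {
        idx <- seq(1, ncol(jf), 3)
        jf[, idx, drop = FALSE]^2 + jf[, idx + 1, drop = FALSE]^2 +
          jf[, idx + 2, drop = FALSE]^2
      }
      sum1[, v0:v1] <- dim3(Re(Y))
      if (two) sum2[, v0:v1] <- dim3(Im(Y))
    }
    for (part in seq_len(if (two) 2 else 1)) {
      pw <- if (part == 1) sum1 else sum2
      tot <- rowSums(pw)                # per time step, across voxels
      if (any(tot <= 0)) stop("zero total power in band ", bn[k + part - 1])
      frac <- colMeans(pw / tot)
      out[, bn[k + part - 1]] <- log(frac[space@roi$voxel])
    }
    k <- k + 2
  }
  out
}

#' ROI-level mixing (crosstalk) matrix of an inverse operator
#'
#' For single-voxel ROIs with fixed radial dipole orientations, the scalar
#' extraction of ROI i is w_i = r_i' T_i (the radial projection of the
#' operator rows at the ROI voxel). The ROI-level mixing matrix
#' C[i, j] = w_i H L_j r_j quantifies how much a unit radial source at ROI j
#' leaks into ROI i's estimated series — the volume-conduction /
#' inverse-smearing confound at ROI level. It is computable from the forward
#' and inverse operators alone.
#'
#' @param operator an \linkS4class{InverseOperator}.
#' @param leadfield the matching \linkS4class{LeadField}.
#' @param space the \linkS4class{SolutionSpace} with ROI definitions.
#' @return List with W (ROIs x electrodes extraction rows), C (ROIs x ROIs
#'   mixing matrix), roi (ROI names).
#' @export
roiMixingMatrix <- function(operator, leadfield, space) {
  roi <- space@roi
  if (!nrow(roi)) stop("solution space has no ROIs")
  E <- length(operator@montage)
  k <- nrow(roi)
  W <- matrix(0, k, E, dimnames = list(roi$roi, operator@montage))
  Lr <- matrix(0, E, k)
  G <- leadfield@gain
  for (i in seq_len(k)) {
    v <- roi$voxel[i]
    p <- space@coords[v, ]
    r <- p / sqrt(sum(p^2))
    W[i, ] <- r %*% operator@T[(3 * v - 2):(3 * v), , drop = FALSE]
    Lr[, i] <- G[, (3 * v - 2):(3 * v), drop = FALSE] %*% r
  }
  H <- diag(E) - matrix(1 / E, E, E)
  C <- W %*% H %*% Lr
  list(W = W, C = C, roi = roi$roi)
}

#' Crosstalk-corrected scalar ROI series
#'
#' Extracts one scalar series per ROI from a common-average referenced
#' recording by applying the inverse of the ROI-level mixing matrix to the
#' radial voxel extractions: est = C^-1 W phi(t). On the atlas ROIs this
#' removes the mutual leakage exactly (the corrected mixing matrix is the
#' identity), at the price of amplifying sensor noise; it is the
#' resolution-based leakage correction used for directed-connectivity
#' analyses, where zero-lag mixing otherwise produces spurious couplings in
#' both directions.
#'
#' @inheritParams roiMixingMatrix
#' @param recording a common-average referenced \linkS4class{EEGRecording}.
#' @return ROIs x samples matrix with ROI rownames; sampling rate in
#'   attribute \code{"fs"}.
#' @export
crosstalkCorrectedSeries <- function(operator, leadfield, space, recording) {
  stopifnot(is(recording, "EEGRecording"))
  if (recording@reference != "common_average")
    stop("apply commonAverageReference() first")
  mm <- roiMixingMatrix(operator, leadfield, space)
  if (kappa(mm$C) > 1e8)
    stop("ROI mixing matrix is numerically singular; ROIs too close for ",
         "crosstalk correction on this grid")
  est <- solve(mm$C, mm$W %*% recording@data)
  rownames(est) <- mm$roi
  attr(est, "fs") <- recording@fs
  est
}

#' Extract per-ROI 3-component current time series
#'
#' Returns the three orientation series at each ROI's single voxel.
#'
#' @param cd a \linkS4class{CurrentDensity}.
#' @param space the \linkS4class{SolutionSpace} with ROI definitions.
#' @return Named list (per ROI) of 3 x samples matrices; sampling rate in
#'   attribute \code{"fs"}.
#' @export
roiTimeSeries <- function(cd, space) {
  stopifnot(is(cd, "CurrentDensity"), is(space, "SolutionSpace"))
  if (!nrow(space@roi)) stop("solution space has no ROIs")
  out <- lapply(seq_len(nrow(space@roi)), function(i) {
    v <- space@roi$voxel[i]
    cd@j[(3 * v - 2):(3 * v), , drop = FALSE]
  })
  names(out) <- space@roi$roi
  attr(out, "fs") <- cd@fs
  out
}
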