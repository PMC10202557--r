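#' Default region-of-interest coordinates
#'
#' Head-frame (mm, origin at the sphere centre) coordinates approximating the
#' seven single-voxel regions of interest: left/right auditory cortex (AUD),
#' left/right somatosensory cortex (SOM), left/right parahippocampus (PHC) and
#' the midline pregenual anterior cingulate cortex (pgACC, one ROI: laterality
#' so close to the midline is not resolvable under volume conduction). These
#' are declared fixture approximations on the spherical head model, not
#' reproductions of any atlas, and can be overridden with user coordinates.
#'
#' @return data.frame with columns roi, x, y, z.
#' @export
defaultROIs <- function() {
  data.frame(
    roi = c("lAUD", "rAUD", "lSOM", "rSOM", "lPHC", "rPHC", "pgACC"),
    x = c(-62, 62, -42, 42, -30, 30, 0),
    y = c(-18, -18, -28, -28, -52, -52, 42),
    z = c(2, 2, 52, 52, -28, -28, 4)
  )
}

gridPresets <- function() {
  # lattice spacing (mm) and exact voxel count per preset; voxels are the
  # innermost `n` points of a half-spacing-offset cubic lattice inside a
  # 78 mm brain ball.
  list(
    mini = list(spacing = 20, n = 160),
    test = list(spacing = 15.5, n = 500),
    paper6239 = list(spacing = 6.5, n = 6239)
  )
}

#' Build a spherical-shell solution space
#'
#' Voxel centres are cubic-lattice points (offset half a spacing from the
#' origin so no voxel sits at the exact centre) inside a 78 mm brain sphere;
#' the preset's exact voxel count is obtained by keeping the innermost points,
#' with lexicographic (z, y, x) tie-breaking. Presets: \code{mini} (160
#' voxels, fast unit tests), \code{test} (500), \code{paper6239} (6239, the
#' paper-scale count).
#'
#' @param preset grid preset name.
#' @param rois data.frame (roi, x, y, z) of single-voxel ROIs, snapped to the
#'   nearest grid voxel; \code{NULL} for no ROIs.
#' @param brain_radius_mm radius of the voxel-bearing sphere (default 78).
#' @return A \linkS4class{SolutionSpace}.
#' @examples
#' solutionSpace("mini")
#' @export
solutionSpace <- function(preset = c("mini", "test", "paper6239"),
                          rois = defaultROIs(), brain_radius_mm = 78) {
  preset <- match.arg(preset)
  spec <- gridPresets()[[preset]]
  h <- spec$spacing
  kmax <- ceiling(brain_radius_mm / h)
  g <- seq(-kmax, kmax) * h + h / 2
  coords <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(coords^2))
  keep <- r <= brain_radius_mm
  coords <- coords[keep, , drop = FALSE]
  r <- r[keep]
  ord <- order(r, coords[, 3], coords[, 2], coords[, 1])
  if (length(ord) < spec$n)
    stop("lattice too coarse for preset voxel count")
  coords <- coords[ord[seq_len(spec$n)], , drop = FALSE]
  rownames(coords) <- NULL
  roiTab <- data.frame(roi = character(), x = numeric(), y = numeric(),
                       z = numeric(), voxel = integer())
  if (!is.null(rois) && nrow(rois)) {
    vox <- vapply(seq_len(nrow(rois)), function(i) {
      d2 <- (coords[, 1] - rois$x[i])^2 + (coords[, 2] - rois$y[i])^2 +
        (coords[, 3] - rois$z[i])^2
      which.min(d2)
    }, 1L)
    roiTab <- data.frame(roi = rois$roi, x = rois$x, y = rois$y, z = rois$z,
                         voxel = vox)
  }
  new("SolutionSpace", coords = coords, voxelSize = h, roi = roiTab,
      preset = preset)
}

# ---- three-shell spherical forward model ------------------------------------
# Concentric-spheres volume conductor (brain | skull | scalp) solved per
# spherical-harmonic degree n. For each degree the radial solution in the
# innermost layer is s_n r^-(n+1) + A1 r^n (s_n the free-medium dipole
# coefficient) and A_j r^n + B_j r^-(n+1) in the outer layers; continuity of
# potential and radial current at the two interfaces plus zero current at the
# scalp give a 5x5 linear system whose scalp-surface solution is linear in
# s_n. The resulting per-degree transfer factors t_n depend only on radii and
# conductivities and are computed once.
shellTransfer <- function(radii, sigma, nmax) {
  # radii are normalized internally by the scalp radius to keep the per-degree
  # linear systems well conditioned; the caller rescales (see buildLeadField).
  r1 <- radii[1] / radii[3]; r2 <- radii[2] / radii[3]; r3 <- 1
  s1 <- sigma[1]; s2 <- sigma[2]; s3 <- sigma[3]
  t_n <- numeric(nmax)
  for (n in seq_len(nmax)) {
    # unknowns: A1, A2, B2, A3, B3 ; source coefficient set to 1
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # potential continuity at r1: A1 r1^n - A2 r1^n - B2 r1^-(n+1) = -r1^-(n+1)
    M[1, ] <- c(r1^n, -r1^n, -r1^-(n + 1), 0, 0)
    rhs[1] <- -r1^-(n + 1)
    # current continuity at r1
    M[2, ] <- c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
                s2 * (n + 1) * r1^-(n + 2), 0, 0)
    rhs[2] <- s1 * (n + 1) * r1^-(n + 2)
    # potential continuity at r2
    M[3, ] <- c(0, r2^n, r2^-(n + 1), -r2^n, -r2^-(n + 1))
    # current continuity at r2
    M[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^-(n + 2),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^-(n + 2))
    # zero radial current at scalp surface r3
    M[5, ] <- c(0, 0, 0, n * r3^(n - 1), -(n + 1) * r3^-(n + 2))
    cs <- apply(abs(M), 2, max)
    sol <- solve(M %*% diag(1 / cs), rhs) / cs
    t_n[n] <- sol[4] * r3^n + sol[5] * r3^-(n + 1)
  }
  t_n
}

# Associated Legendre P_n(x) and P_n^1(x) for n = 1..nmax at a vector x,
# by the standard upward recurrences. Returns list of nmax x length(x)
# matrices.
legendreP01 <- function(x, nmax) {
  nx <- length(x)
  P0 <- matrix(0, nmax, nx)   # P_n
  P1 <- matrix(0, nmax, nx)   # P_n^1
  s <- sqrt(pmax(0, 1 - x^2))
  P0[1, ] <- x
  if (nmax >= 2) P0[2, ] <- 0.5 * (3 * x^2 - 1)
  P1[1, ] <- -s
  if (nmax >= 2) P1[2, ] <- -3 * x * s
  if (nmax >= 3) for (n in 3:nmax) {
    P0[n, ] <- ((2 * n - 1) * x * P0[n - 1, ] - (n - 1) * P0[n - 2, ]) / n
    P1[n, ] <- ((2 * n - 1) * x * P1[n - 1, ] - n * P1[n - 2, ]) / (n - 1)
  }
  list(P = P0, P1 = P1)
}

#' Build a lead field for a montage over a solution space
#'
#' \code{model = "three_shell_sphere"} evaluates the closed-form series
#' solution of a dipole in three concentric spheres (brain, skull, scalp;
#' default radii 78/86/92 mm and conductivity ratios 1 : 1/80 : 1) at the
#' electrode positions. \code{model = "synthetic"} draws a seeded random
#' full-row-rank gain, for tests that need an arbitrary well-conditioned
#' forward model.
#'
#' @param montage electrodes x 3 position matrix with rownames, e.g.
#'   \code{standard1020Positions()}.
#' @param space a \linkS4class{SolutionSpace}.
#' @param model "three_shell_sphere" or "synthetic".
#' @param radii_mm radii of brain, skull and scalp spheres.
#' @param conductivity relative conductivities of the three shells.
#' @param nmax series truncation degree.
#' @param seed seed for the synthetic model.
#' @return A \linkS4class{LeadField}; columns grouped per voxel as (x, y, z)
#'   unit dipole moments.
#' @export
buildLeadField <- function(montage, space,
                           model = c("three_shell_sphere", "synthetic"),
                           radii_mm = c(78, 86, 92),
                           conductivity = c(1, 1 / 80, 1),
                           nmax = 80, seed = 1) {
  model <- match.arg(model)
  stopifnot(is(space, "SolutionSpace"), ncol(montage) == 3, nrow(montage) >= 8)
  coords <- space@coords
  nV <- nrow(coords)
  nE <- nrow(montage)
  if (model == "synthetic") {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    G <- matrix(stats::rnorm(nE * 3 * nV), nE, 3 * nV)
    return(new("LeadField", gain = G, model = "synthetic",
               montage = rownames(montage), positions = as.matrix(montage)))
  }
  rmax <- sqrt(max(rowSums(coords^2)))
  if (rmax >= radii_mm[1])
    stop("voxel outside the innermost (brain) shell")
  t_n <- shellTransfer(radii_mm, conductivity, nmax)
  eDir <- montage / sqrt(rowSums(montage^2))   # electrodes on scalp sphere
  ns <- seq_len(nmax)
  G <- matrix(0, nE, 3 * nV)
  for (v in seq_len(nV)) {
    p <- coords[v, ]
    f <- sqrt(sum(p^2))
    if (f < 1e-9) {
      zh <- c(0, 0, 1); xh <- c(1, 0, 0); yh <- c(0, 1, 0)
    } else {
      zh <- p / f
      ref <- if (abs(zh[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      xh <- ref - sum(ref * zh) * zh
      xh <- xh / sqrt(sum(xh^2))
      yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
              zh[3] * xh[1] - zh[1] * xh[3],
              zh[1] * xh[2] - zh[2] * xh[1])
    }
    cg <- as.vector(eDir %*% zh)                    # cos(gamma) per electrode
    sg <- sqrt(pmax(0, 1 - cg^2))
    ex <- as.vector(eDir %*% xh)
    ey <- as.vector(eDir %*% yh)
    cph1 <- ifelse(sg > 1e-12, ex / sg, 0)
    cph2 <- ifelse(sg > 1e-12, ey / sg, 0)
    L <- legendreP01(cg, nmax)
    # t_n is for the unit-outer-radius geometry; rescale to physical units
    radialCoef <- t_n * (f / radii_mm[3])^(ns - 1) /
      (4 * pi * conductivity[1] * radii_mm[3]^2)
    Vr <- as.vector(t(L$P) %*% (radialCoef * ns))   # radial unit moment
    Vt <- as.vector(t(L$P1) %*% radialCoef)         # tangential pattern
    # (P_n^1 carries a conventional (-1) Condon-Shortley factor; the free-
    # medium expansion used here takes +q_t P_n^1 cos(phi) with that factor
    # absorbed, checked against the direct infinite-medium dipole potential.)
    V1 <- -Vt * cph1
    V2 <- -Vt * cph2
    B <- rbind(zh, xh, yh)
    G[, (3 * v - 2):(3 * v)] <- cbind(Vr, V1, V2) %*% B
  }
  new("LeadField", gain = G, model = "three_shell_sphere",
      montage = rownames(montage), positions = as.matrix(montage))
}

# Direct infinite-medium dipole potential (oracle for the series' source term).
infiniteMediumPotential <- function(rObs, rDip, q, sigma = 1) {
  d <- rObs - matrix(rDip, nrow(rObs), 3, byrow = TRUE)
  dn <- sqrt(rowSums(d^2))
  as.vector(d %*% q) / (4 * pi * sigma * dn^3)
}
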