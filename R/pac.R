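#' First principal component of a band-filtered 3-component current
#'
#' Band-passes each of the three orientation series (zero-phase), then
#' projects onto the first principal axis of their 3x3 covariance. Sign
#' convention: the component is flipped, if necessary, to correlate
#' positively with the largest-variance filtered orientation series.
#'
#' @param xyz 3 x samples matrix (the three orientation series of one ROI
#'   voxel).
#' @param fs sampling rate in Hz.
#' @param band c(lo, hi) in Hz; \code{NULL} to skip filtering.
#' @return Numeric vector (samples); proportion of variance captured in
#'   attribute \code{"varExplained"}.
#' @export
bandPC1 <- function(xyz, fs, band = NULL) {
  stopifnot(nrow(xyz) == 3, ncol(xyz) >= 3)
  if (all(xyz == 0)) stop("all-zero input: principal component undefined")
  y <- if (is.null(band)) t(xyz) else fftBandpass(t(xyz), fs, band[1], band[2])
  C <- stats::cov(y)
  e <- eigen(C, symmetric = TRUE)
  w <- e$vectors[, 1]
  ref <- which.max(diag(C))
  if (sum(w * C[, ref]) < 0) w <- -w
  pc <- as.vector(y %*% w)
  attr(pc, "varExplained") <- e$values[1] / sum(e$values)
  pc
}

#' Phase-amplitude coupling by normalized mean vector length
#'
#' theta(t) is the instantaneous phase of the analytic low-frequency series
#' (phase 0 at the oscillation peak) and a(t) the analytic envelope of the
#' high-frequency series; the coupling statistic is
#' mvl = |mean(a e^(i theta))| / mean(a). One second is trimmed at each end
#' after the Hilbert transforms to suppress analytic-signal edge artifacts.
#' For a planted envelope a = 1 + m cos(theta) with uniform phase coverage
#' the expectation is m/2.
#'
#' @param theta_series band-limited low-frequency (phase-providing) series.
#' @param gamma_series band-limited high-frequency (amplitude) series.
#' @param fs sampling rate in Hz.
#' @return List with mvl, n (samples used after trimming).
#' @export
pacMvl <- function(theta_series, gamma_series, fs) {
  if (length(theta_series) != length(gamma_series))
    stop("series lengths differ")
  ph <- Arg(analyticSignal(theta_series))
  env <- Mod(analyticSignal(gamma_series))
  keep <- pacTrimIndex(length(ph), fs)
  ph <- ph[keep]; env <- env[keep]
  mvl <- Mod(mean(env * exp(1i * ph))) / mean(env)
  list(mvl = mvl, n = length(keep))
}

pacTrimIndex <- function(n, fs) {
  trim <- round(fs)
  if (n <= 2 * trim + 2) stop("series too short for 1 s edge trimming")
  (trim + 1):(n - trim)
}

#' Surrogate z-score for phase-amplitude coupling
#'
#' Surrogates circularly time-shift the (trimmed) gamma envelope against the
#' theta phase by uniform random offsets of at least 1 s, destroying the
#' phase-amplitude alignment while preserving both marginals;
#' z = (mvl - mean(surrogates)) / sd(surrogates). The full surrogate set is
#' evaluated at once through an FFT circular cross-correlation of the
#' envelope with e^(i theta) (identical values to explicit shifting).
#'
#' @inheritParams pacMvl
#' @param n_surrogates number of surrogate shifts (>= 200).
#' @param seed RNG seed for the shift draws.
#' @return List with mvl, z, n_surrogates, seed.
#' @export
pacZscore <- function(theta_series, gamma_series, fs, n_surrogates = 200,
                      seed = 1) {
  if (n_surrogates < 200) stop("need at least 200 surrogates")
  if (length(theta_series) < 2 * fs) stop("series shorter than 2 s")
  if (length(theta_series) != length(gamma_series))
    stop("series lengths differ")
  ph <- Arg(analyticSignal(theta_series))
  env <- Mod(analyticSignal(gamma_series))
  keep <- pacTrimIndex(length(ph), fs)
  ph <- ph[keep]; env <- env[keep]
  n <- length(ph)
  z <- exp(1i * ph)
  denom <- sum(env)
  mvl <- Mod(sum(env * z)) / denom
  minShift <- round(fs)
  if (n - 2 * minShift < n_surrogates / 2)
    stop("series too short for >= 1 s circular shifts")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  shifts <- sample(minShift:(n - minShift), n_surrogates, replace = TRUE)
  # C(s+1) = sum_t env((t+s-1) mod n + 1) * z(t), all s at once via FFT
  C <- stats::fft(stats::fft(env) * Conj(stats::fft(Conj(z))), inverse = TRUE) / n
  mvlShift <- Mod(C[shifts + 1]) / denom
  zscore <- (mvl - mean(mvlShift)) / stats::sd(mvlShift)
  list(mvl = mvl, z = zscore, n_surrogates = n_surrogates, seed = seed)
}

#' PAC table over ROIs
#'
#' Computes theta-phase / gamma-amplitude coupling per ROI from the 3-component
#' source currents: band PC1 in each band, then the normalized mean vector
#' length with its surrogate z-score.
#'
#' @param roiXYZ named list of 3 x samples matrices (per-ROI currents).
#' @param fs sampling rate in Hz.
#' @param phase_band,amp_band band edges (defaults theta, gamma).
#' @param n_surrogates,seed surrogate settings.
#' @return data.frame: roi, mvl, z, n_surrogates, seed.
#' @export
pacTable <- function(roiXYZ, fs, phase_band = defaultBands()$theta,
                     amp_band = defaultBands()$gamma, n_surrogates = 200,
                     seed = 1) {
  rows <- lapply(names(roiXYZ), function(r) {
    th <- bandPC1(roiXYZ[[r]], fs, phase_band)
    ga <- bandPC1(roiXYZ[[r]], fs, amp_band)
    res <- pacZscore(th, ga, fs, n_surrogates, seed)
    data.frame(roi = r, mvl = res$mvl, z = res$z,
               n_surrogates = n_surrogates, seed = seed)
  })
  do.call(rbind, rows)
}
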