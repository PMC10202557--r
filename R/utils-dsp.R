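#' Canonical frequency bands
#'
#' The five analysis bands, as half-open intervals [lo, hi) in Hz: delta
#' (2-3.5), theta (4-7.5), alpha (8-12), beta (13-30), gamma (30.5-44).
#' All lie inside the 2-44 Hz analysis range.
#'
#' @return Named list of two-element numeric vectors c(lo, hi).
#' @examples
#' defaultBands()$theta
#' @export
defaultBands <- function() {
  list(delta = c(2, 3.5), theta = c(4, 7.5), alpha = c(8, 12),
       beta = c(13, 30), gamma = c(30.5, 44))
}

validateBands <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  for (b in names(bands)) {
    v <- bands[[b]]
    if (length(v) != 2 || v[1] >= v[2])
      stop("band '", b, "' must be c(lo, hi) with lo < hi")
  }
  invisible(bands)
}

#' Quarter-cycle lag and period of an oscillation
#'
#' The sine component of a Fourier pair lags the cosine by a quarter of the
#' oscillation period, which is inversely proportional to frequency: 25 ms at
#' 10 Hz, 12.5 ms at 20 Hz. Used to interpret lagged-coherence delays.
#'
#' @param freq_hz oscillation frequency in Hz.
#' @return For \code{quarterCycleLag}, the quarter-period in milliseconds; for
#'   \code{oscillationPeriod}, the full period in milliseconds.
#' @examples
#' quarterCycleLag(10)    # 25 ms
#' oscillationPeriod(10)  # 100 ms
#' @export
quarterCycleLag <- function(freq_hz) {
  stopifnot(all(freq_hz > 0))
  1000 / (4 * freq_hz)
}

#' @rdname quarterCycleLag
#' @export
oscillationPeriod <- function(freq_hz) {
  stopifnot(all(freq_hz > 0))
  1000 / freq_hz
}

# Zero-phase band-pass by frequency-domain multiplication with a real,
# symmetric transfer function having raised-cosine transitions of width `tw`
# Hz centred on the cut-offs. Operates column-wise on a matrix (time in rows).
# A real symmetric response has exactly zero phase; circular edge effects are
# the price, acceptable for the multi-minute records used here.
fftBandpass <- function(x, fs, lo, hi, tw = 0.5) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  f <- fftFreqs(n, fs)
  H <- raisedCosineResponse(abs(f), lo, hi, tw)
  X <- stats::mvfft(x)
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / n
  if (vec) drop(y) else y
}

fftFreqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

raisedCosineResponse <- function(fa, lo, hi, tw) {
  H <- numeric(length(fa))
  H[fa >= lo + tw / 2 & fa <= hi - tw / 2] <- 1
  rampUp <- fa > lo - tw / 2 & fa < lo + tw / 2
  H[rampUp] <- 0.5 * (1 - cos(pi * (fa[rampUp] - (lo - tw / 2)) / tw))
  rampDown <- fa > hi - tw / 2 & fa < hi + tw / 2
  H[rampDown] <- 0.5 * (1 + cos(pi * (fa[rampDown] - (hi - tw / 2)) / tw))
  H
}

# Band-limited sampling-rate conversion by Fourier-domain truncation /
# zero-padding. Assumes the signal has already been low-passed below the
# target Nyquist (the 2-44 Hz analysis band-pass guarantees this for the
# 128 Hz target).
fftResample <- function(x, fs_in, fs_out) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n_in <- nrow(x)
  n_out <- floor(n_in * fs_out / fs_in)
  X <- stats::mvfft(x)
  Y <- matrix(0 + 0i, n_out, ncol(x))
  nh <- min(floor((n_in - 1) / 2), floor((n_out - 1) / 2))
  Y[1, ] <- X[1, ]
  if (nh > 0) {
    Y[2:(nh + 1), ] <- X[2:(nh + 1), ]
    Y[(n_out - nh + 1):n_out, ] <- X[(n_in - nh + 1):n_in, ]
  }
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n_out * (n_out / n_in)
  if (vec) drop(y) else y
}

# Analytic signal via the standard one-sided spectrum construction.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Gaussian white noise filtered into [lo, hi) with the zero-phase band-pass,
# scaled to unit RMS. The draw consumes the current RNG stream.
narrowbandNoise <- function(n, fs, lo, hi, ncol = 1) {
  x <- matrix(stats::rnorm(n * ncol), n, ncol)
  y <- fftBandpass(x, fs, lo, hi)
  sweep(y, 2, sqrt(colMeans(y^2)), "/")
}

# 1/f-amplitude ("pink") noise band-limited to [lo, hi], unit RMS per column.
# Emulates the spectral slope of resting EEG background activity.
pinkNoise <- function(n, fs, lo = 2, hi = 44, ncol = 1) {
  x <- matrix(stats::rnorm(n * ncol), n, ncol)
  f <- abs(fftFreqs(n, fs))
  H <- raisedCosineResponse(f, lo, hi, 0.5) / sqrt(pmax(f, lo))
  y <- Re(stats::mvfft(stats::mvfft(x) * H, inverse = TRUE)) / n
  sweep(y, 2, sqrt(colMeans(y^2)), "/")
}

# Fraction of periodogram power inside [lo, hi].
bandPowerFraction <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- abs(fftFreqs(n, fs))
  keep <- f >= lo & f <= hi
  sum(P[keep]) / sum(P[-1])
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix via eigendecomposition.
symPinv <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Deterministic per-subject seed derivation from a master seed.
deriveSeeds <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
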