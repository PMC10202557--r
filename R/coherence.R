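#' Complex coherency between two channels in a band
#'
#' c = S_xy / sqrt(S_xx S_yy) computed from the band-averaged cross-spectral
#' matrix. The \code{"phase"} variant recomputes the band cross-spectra from
#' unit-modulus (amplitude-normalized) Fourier coefficients, giving the
#' phase-synchronization form.
#'
#' @param cross a \linkS4class{BandCrossSpectra}.
#' @param i,j channel indices or labels (i != j).
#' @param band band name.
#' @param form "coherence" (raw coefficients) or "phase" (unit-modulus).
#' @return List with fields i, j, band, form, c (complex), nEpochs.
#' @export
complexCoherency <- function(cross, i, j, band,
                             form = c("phase", "coherence")) {
  stopifnot(is(cross, "BandCrossSpectra"))
  form <- match.arg(form)
  if (is.character(i)) i <- match(i, cross@channelLabels)
  if (is.character(j)) j <- match(j, cross@channelLabels)
  if (anyNA(c(i, j))) stop("unknown channel label")
  if (i == j) stop("coherency requires two distinct channels")
  if (!band %in% names(cross@bands)) stop("unknown band: ", band)
  S <- bandPairSpectrum(cross, i, j, band, form)
  if (Re(S$sxx) <= 0 || Re(S$syy) <= 0)
    stop("zero auto-spectrum: coherency undefined")
  cc <- S$sxy / sqrt(Re(S$sxx) * Re(S$syy))
  list(i = i, j = j, band = band, form = form, c = cc, nEpochs = cross@nEpochs)
}

# Band-averaged 2x2 spectra for a channel pair, optionally from unit-modulus
# coefficients, optionally with epoch pairing permuted for surrogates.
bandPairSpectrum <- function(cross, i, j, band, form, permute = NULL) {
  cf <- cross@coef[[band]]
  xi <- cf[i, , , drop = TRUE]
  xj <- cf[j, , , drop = TRUE]
  if (is.null(dim(xi))) { xi <- matrix(xi, nrow = 1); xj <- matrix(xj, nrow = 1) }
  if (form == "phase") {
    xi <- xi / pmax(Mod(xi), .Machine$double.eps)
    xj <- xj / pmax(Mod(xj), .Machine$double.eps)
  }
  if (!is.null(permute)) xj <- xj[, permute, drop = FALSE]
  list(sxx = mean(Mod(xi)^2), syy = mean(Mod(xj)^2),
       sxy = mean(xi * Conj(xj)))
}

#' Lagged phase coherence from a complex coherency
#'
#' The component of coherence attributable only to non-instantaneous (lagged)
#' dependence: LC = Im(c)^2 / (1 - Re(c)^2). Instantaneous (volume-conducted)
#' dependence is purely real and contributes nothing. When Re(c) = +-1 (pure
#' zero-lag dependence) the value is defined as 0, with a warning.
#'
#' @param coherency result of \code{complexCoherency}, or a complex scalar.
#' @return Value in [0, 1).
#' @examples
#' laggedPhaseCoherence(0.5i)        # 0.25
#' laggedPhaseCoherence(0.6 + 0i)    # 0
#' @export
laggedPhaseCoherence <- function(coherency) {
  cc <- if (is.list(coherency)) coherency$c else coherency
  re <- Re(cc); im <- Im(cc)
  if (abs(abs(re) - 1) < 1e-12) {
    warning("Re(c) = +-1: pure zero-lag dependence carries no lagged component")
    return(0)
  }
  if (abs(re) > 1) stop("invalid coherency: |Re(c)| > 1")
  val <- im^2 / (1 - re^2)
  min(val, 1 - .Machine$double.eps)
}

#' Significance of a lagged phase coherence value
#'
#' \code{method = "surrogate"} (default) randomizes the sign of the
#' imaginary part of each epoch's cross-spectral contribution while keeping
#' the real part: under the null hypothesis that all dependence is
#' instantaneous (purely real coherency) the per-epoch imaginary parts are
#' exchangeable with their negatives, so this tests exactly the lagged
#' component while preserving any volume-conducted (zero-lag) dependence in
#' the null distribution. The p-value is the rank of the observed value
#' among the surrogates. \code{method = "asymptotic"} uses the large-sample
#' chi-square approximation for the lagged statistic:
#' -2m log(1 - LC) ~ chi2(1) with m the number of averaged coefficient pairs.
#'
#' @param cross a \linkS4class{BandCrossSpectra}.
#' @param i,j channel indices or labels.
#' @param band band name.
#' @param form coherency form, as in \code{complexCoherency}.
#' @param method "surrogate" or "asymptotic".
#' @param n_shuffles surrogate count (default 500).
#' @param seed RNG seed for the shuffles.
#' @return List with lpc, p, method, n_shuffles.
#' @export
lpcSignificance <- function(cross, i, j, band, form = c("phase", "coherence"),
                            method = c("surrogate", "asymptotic"),
                            n_shuffles = 500, seed = 1) {
  form <- match.arg(form)
  method <- match.arg(method)
  obs <- laggedPhaseCoherence(complexCoherency(cross, i, j, band, form))
  if (is.character(i)) i <- match(i, cross@channelLabels)
  if (is.character(j)) j <- match(j, cross@channelLabels)
  if (method == "asymptotic") {
    m <- cross@nEpochs * dim(cross@coef[[band]])[2]
    p <- stats::pchisq(-2 * m * log(1 - obs), df = 1, lower.tail = FALSE)
    return(list(lpc = obs, p = max(p, .Machine$double.xmin), method = method,
                n_shuffles = NA_integer_))
  }
  if (cross@nEpochs < 8)
    stop("surrogate method needs at least 8 epochs")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nE <- cross@nEpochs
  # per-epoch band-mean cross terms and auto powers
  cf <- cross@coef[[band]]
  xi <- cf[i, , , drop = TRUE]; xj <- cf[j, , , drop = TRUE]
  if (is.null(dim(xi))) { xi <- matrix(xi, nrow = 1); xj <- matrix(xj, nrow = 1) }
  if (form == "phase") {
    xi <- xi / pmax(Mod(xi), .Machine$double.eps)
    xj <- xj / pmax(Mod(xj), .Machine$double.eps)
  }
  crossE <- colMeans(xi * Conj(xj))     # one complex value per epoch
  denom <- sqrt(mean(Mod(xi)^2) * mean(Mod(xj)^2))
  reE <- Re(crossE); imE <- Im(crossE)
  exceed <- 0L
  for (s in seq_len(n_shuffles)) {
    flips <- sample(c(-1, 1), nE, replace = TRUE)
    cc <- complex(real = mean(reE), imaginary = mean(flips * imE)) / denom
    v <- Im(cc)^2 / max(1 - Re(cc)^2, .Machine$double.eps)
    if (v >= obs) exceed <- exceed + 1L
  }
  list(lpc = obs, p = (exceed + 1) / (n_shuffles + 1), method = method,
       n_shuffles = n_shuffles)
}

#' Lagged-phase-coherence table over ROI pairs and bands
#'
#' Long-format table of the lagged phase coherence (and optionally its
#' surrogate p-value) for every unordered channel pair and band of a
#' cross-spectra object.
#'
#' @param cross a \linkS4class{BandCrossSpectra} (e.g. built from ROI series).
#' @param bands band names (default: all in \code{cross}).
#' @param form coherency form.
#' @param significance also compute surrogate p-values (slower).
#' @param n_shuffles,seed surrogate settings.
#' @return data.frame with columns roi_i, roi_j, band, lpc (and p).
#' @export
lpcTable <- function(cross, bands = names(cross@bands),
                     form = c("phase", "coherence"), significance = FALSE,
                     n_shuffles = 500, seed = 1) {
  form <- match.arg(form)
  labs <- cross@channelLabels
  pairs <- utils::combn(length(labs), 2)
  rows <- list()
  for (b in bands) {
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (significance) {
        r <- lpcSignificance(cross, i, j, b, form, "surrogate", n_shuffles,
                             seed + k)
        rows[[length(rows) + 1]] <- data.frame(
          roi_i = labs[i], roi_j = labs[j], band = b, lpc = r$lpc, p = r$p)
      } else {
        v <- laggedPhaseCoherence(complexCoherency(cross, i, j, b, form))
        rows[[length(rows) + 1]] <- data.frame(
          roi_i = labs[i], roi_j = labs[j], band = b, lpc = v, p = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
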