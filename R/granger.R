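#' Fit a multivariate autoregressive model by least squares
#'
#' Stacks lagged copies of the demeaned series into a regression design and
#' fits all equations jointly by ordinary least squares. With
#' \code{order = "auto"} the order p in [2, pmax] minimizing the chosen
#' information criterion is selected. Epoch boundaries (optional) are honoured
#' by excluding regression rows whose lag window crosses a boundary, so
#' concatenated segments can be fitted without contaminating the design.
#'
#' @param x samples x k numeric matrix (k series).
#' @param order integer model order, or "auto".
#' @param pmax maximum candidate order for "auto" (default 20).
#' @param criterion "bic" (default) or "aic".
#' @param epochs optional integer vector (length = samples) of segment ids.
#' @return List of class \code{"mvarModel"}: A (k x k x p), p, Sigma,
#'   criterionTable, stable, nObs.
#' @export
fitMVAR <- function(x, order = "auto", pmax = 20, criterion = c("bic", "aic"),
                    epochs = NULL) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  k <- ncol(x)
  n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  if (identical(order, "auto")) {
    cand <- 2:pmax
    crit <- vapply(cand, function(p) mvarCriterion(x, p, criterion, epochs),
                   0.0)
    p <- cand[which.min(crit)]
    critTab <- data.frame(order = cand, criterion = crit)
  } else {
    p <- as.integer(order)
    critTab <- data.frame(order = p,
                          criterion = mvarCriterion(x, p, criterion, epochs))
  }
  if (n < 10 * k * p)
    stop("series too short: need at least 10 * k * p samples")
  fit <- mvarLS(x, p, epochs)
  A <- fit$A; Sigma <- fit$Sigma
  lam <- mvarCompanionRadius(A)
  if (lam >= 1)
    stop(sprintf("fitted model unstable (spectral radius %.3f); ", lam),
         "increase the order or provide more data")
  structure(list(A = A, p = p, Sigma = Sigma, criterionTable = critTab,
                 stable = TRUE, nObs = fit$nObs, k = k),
            class = "mvarModel")
}

mvarDesign <- function(x, p, epochs = NULL) {
  n <- nrow(x); k <- ncol(x)
  rows <- (p + 1):n
  if (!is.null(epochs)) {
    ok <- vapply(rows, function(t) length(unique(epochs[(t - p):t])) == 1L,
                 TRUE)
    rows <- rows[ok]
  }
  X <- matrix(0, length(rows), k * p)
  for (l in seq_len(p))
    X[, ((l - 1) * k + 1):(l * k)] <- x[rows - l, , drop = FALSE]
  list(Y = x[rows, , drop = FALSE], X = X)
}

mvarLS <- function(x, p, epochs = NULL) {
  k <- ncol(x)
  d <- mvarDesign(x, p, epochs)
  B <- qr.solve(d$X, d$Y)                       # (k p) x k
  E <- d$Y - d$X %*% B
  Sigma <- crossprod(E) / (nrow(d$Y) - k * p)
  A <- array(0, c(k, k, p))
  for (l in seq_len(p))
    A[, , l] <- t(B[((l - 1) * k + 1):(l * k), , drop = FALSE])
  list(A = A, Sigma = Sigma, nObs = nrow(d$Y))
}

mvarCriterion <- function(x, p, criterion, epochs = NULL) {
  k <- ncol(x)
  fit <- try(mvarLS(x, p, epochs), silent = TRUE)
  if (inherits(fit, "try-error")) return(Inf)
  n <- fit$nObs
  detS <- det(fit$Sigma)
  if (!is.finite(detS) || detS <= 0) return(Inf)
  pen <- if (criterion == "bic") log(n) else 2
  log(detS) + pen * p * k^2 / n
}

mvarCompanionRadius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) C[1:k, ((l - 1) * k + 1):(l * k)] <- A[, , l]
  if (p > 1) C[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# Spectral matrix of a fitted bivariate MVAR at frequencies f (Hz).
mvarSpectralParts <- function(model, f, fs) {
  k <- model$k; p <- model$p
  lapply(f, function(fr) {
    Af <- diag(k) + 0i
    for (l in seq_len(p))
      Af <- Af - model$A[, , l] * exp(-2i * pi * fr * l / fs)
    H <- solve(Af)
    list(H = H, S = H %*% model$Sigma %*% Conj(t(H)))
  })
}

#' Granger causality between two series
#'
#' Directed coupling from \code{source} to \code{target}. The time-domain
#' value is the log-ratio between the residual variance of the reduced model
#' (target predicted from its own past only) and that of the full bivariate
#' model which adds the source's past. The band-restricted value (used for
#' the theta-band analyses) is the Geweke spectral decomposition of the
#' fitted bivariate model averaged over the band's frequencies; the series
#' are NOT band-pass filtered before fitting, which is known to distort
#' autoregressive causality estimates. Negative estimation noise is floored
#' at 0 and flagged in attribute \code{"floored"}.
#'
#' @param source,target numeric vectors (equal length).
#' @param order model order or "auto".
#' @param band \code{NULL} for the time-domain value, or c(lo, hi) in Hz.
#' @param fs sampling rate (required with \code{band}).
#' @param df frequency step for the band average (default 0.25 Hz).
#' @param epochs optional segment ids (see \code{fitMVAR}).
#' @param pmax maximum candidate order for "auto".
#' @param leakage_correction apply pairwise symmetric (Loewdin)
#'   orthogonalization before fitting, removing the shared zero-lag
#'   component. Source-reconstructed series are instantaneous mixtures of
#'   the true sources (volume conduction and inverse smearing), which
#'   inflates Granger estimates in both directions; orthogonalization is the
#'   standard leakage mitigation for source-space directed connectivity.
#' @return Non-negative scalar GC value.
#' @export
grangerPair <- function(source, target, order = "auto", band = NULL, fs = NULL,
                        df = 0.25, epochs = NULL, pmax = 20,
                        leakage_correction = FALSE) {
  stopifnot(length(source) == length(target))
  if (leakage_correction) {
    o <- lowdinPair(source, target)
    source <- o[, 1]; target <- o[, 2]
  }
  x <- cbind(s = as.numeric(source), t = as.numeric(target))
  full <- fitMVAR(x, order = order, pmax = pmax, epochs = epochs)
  p <- full$p
  if (is.null(band)) {
    red <- mvarLS(matrix(x[, 2] - mean(x[, 2]), ncol = 1), p, epochs)
    val <- log(red$Sigma[1, 1] / full$Sigma[2, 2])
  } else {
    if (is.null(fs)) stop("band-restricted GC needs fs")
    if (band[2] > fs / 2) stop("band outside the Nyquist range")
    f <- seq(band[1], band[2], by = df)
    parts <- mvarSpectralParts(full, f, fs)
    Sig <- full$Sigma
    # conditional source innovation variance given the target innovation
    sTilde <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]
    gcf <- vapply(parts, function(pp) {
      Syy <- Re(pp$S[2, 2])
      intrinsic <- Syy - sTilde * Mod(pp$H[2, 1])^2
      log(Syy / max(intrinsic, .Machine$double.eps))
    }, 0.0)
    val <- mean(gcf)
  }
  floored <- val < 0
  structure(max(val, 0), floored = floored)
}

# Closest orthogonal pair (Loewdin / symmetric orthogonalization) of two
# variance-normalized series: X' = X (X'X)^(-1/2).
lowdinPair <- function(u, v) {
  X <- cbind(u / stats::sd(u), v / stats::sd(v))
  S <- crossprod(X) / nrow(X)
  e <- eigen(S, symmetric = TRUE)
  X %*% (e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-12))))
}

# Both directed band-restricted GC values of one pair from a single
# bivariate fit (the Geweke decomposition yields both directions).
gewekeBoth <- function(u, v, order, band, fs, df = 0.25, epochs = NULL,
                       leakage_correction = FALSE) {
  if (leakage_correction) {
    o <- lowdinPair(u, v)
    u <- o[, 1]; v <- o[, 2]
  }
  full <- fitMVAR(cbind(u, v), order = order, epochs = epochs)
  Sig <- full$Sigma
  f <- seq(band[1], band[2], by = df)
  parts <- mvarSpectralParts(full, f, fs)
  sT1 <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]   # innovation of u given v
  sT2 <- Sig[2, 2] - Sig[1, 2]^2 / Sig[1, 1]
  g12 <- mean(vapply(parts, function(pp) {
    Syy <- Re(pp$S[2, 2])
    log(Syy / max(Syy - sT1 * Mod(pp$H[2, 1])^2, .Machine$double.eps))
  }, 0.0))
  g21 <- mean(vapply(parts, function(pp) {
    Sxx <- Re(pp$S[1, 1])
    log(Sxx / max(Sxx - sT2 * Mod(pp$H[1, 2])^2, .Machine$double.eps))
  }, 0.0))
  c(fwd = max(g12, 0), rev = max(g21, 0),
    floored_fwd = g12 < 0, floored_rev = g21 < 0)
}

#' The 22-link directed roster
#'
#' All directed links analysed at ROI level: pgACC with left/right AUD, SOM
#' and PHC in both directions (12), auditory and somatosensory cortex with
#' the parahippocampus within hemisphere in both directions (8), and the two
#' interhemispheric parahippocampal links.
#'
#' @return data.frame with columns source, target.
#' @export
gcLinkRoster <- function() {
  hub <- c("lAUD", "rAUD", "lSOM", "rSOM", "lPHC", "rPHC")
  out <- rbind(
    data.frame(source = "pgACC", target = hub),
    data.frame(source = hub, target = "pgACC"),
    data.frame(source = c("lAUD", "lPHC", "rAUD", "rPHC",
                          "lSOM", "lPHC", "rSOM", "rPHC"),
               target = c("lPHC", "lAUD", "rPHC", "rAUD",
                          "lPHC", "lSOM", "rPHC", "rSOM")),
    data.frame(source = c("lPHC", "rPHC"), target = c("rPHC", "lPHC"))
  )
  rownames(out) <- NULL
  out
}

#' Granger-causality table for one subject's ROI series
#'
#' Fills the full 22-link roster with pairwise bivariate band-restricted GC
#' values, recording the order used and stability per link.
#'
#' @param roiSeries named list of 1-D ROI series (all 7 ROIs present), e.g.
#'   first principal components of the source currents.
#' @param fs sampling rate in Hz.
#' @param band c(lo, hi) in Hz (default theta).
#' @param order model order or "auto" (default 12; one fixed order keeps the
#'   22 fits comparable, and must be large enough to model the superimposed
#'   band-limited components).
#' @param epochs optional segment ids.
#' @param leakage_correction see \code{grangerPair}.
#' @return data.frame: source_roi, target_roi, band_lo, band_hi, gc, order_p,
#'   stable, floored.
#' @export
gcTable <- function(roiSeries, fs, band = defaultBands()$theta, order = 12,
                    epochs = NULL, leakage_correction = FALSE) {
  roster <- gcLinkRoster()
  need <- unique(c(roster$source, roster$target))
  miss <- setdiff(need, names(roiSeries))
  if (length(miss)) stop("missing ROI series: ", paste(miss, collapse = ", "))
  if (identical(order, "auto"))
    stop("gcTable uses one fixed order across the roster; pass an integer")
  pairKey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(roster)), function(k) {
    src <- roster$source[k]; tgt <- roster$target[k]
    key <- pairKey(src, tgt)
    if (is.null(cache[[key]])) {
      a <- sort(c(src, tgt))
      cache[[key]] <- gewekeBoth(roiSeries[[a[1]]], roiSeries[[a[2]]],
                                 order = order, band = band, fs = fs,
                                 epochs = epochs,
                                 leakage_correction = leakage_correction)
    }
    g <- cache[[key]]
    fwd <- src == sort(c(src, tgt))[1]
    data.frame(source_roi = src, target_roi = tgt,
               band_lo = band[1], band_hi = band[2],
               gc = unname(if (fwd) g["fwd"] else g["rev"]),
               order_p = as.integer(order), stable = TRUE,
               floored = unname(if (fwd) g["floored_fwd"] else g["floored_rev"]) > 0)
  })
  do.call(rbind, rows)
}
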