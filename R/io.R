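#' Standard 10-20 electrode positions on a spherical scalp
#'
#' Unit-sphere positions for the 19-channel International 10-20 montage,
#' constructed from the proportional placement rules on a sphere (x to the
#' right ear, y to the nasion, z up), scaled to the given scalp radius.
#' Interior electrodes (F3/F4, P3/P4) are placed at the spherical midpoint of
#' their neighbouring standard sites, as in the 10-20 arc construction.
#'
#' @param radius_mm scalp sphere radius in mm (default 92).
#' @return Matrix 19 x 3 with rownames the channel labels.
#' @examples
#' head(standard1020Positions())
#' @export
standard1020Positions <- function(radius_mm = 92) {
  sph <- function(polar_deg, azim_deg) {
    p <- polar_deg * pi / 180; a <- azim_deg * pi / 180
    c(sin(p) * cos(a), sin(p) * sin(a), cos(p))
  }
  slerpMid <- function(u, v) {
    w <- u + v
    w / sqrt(sum(w^2))
  }
  pos <- list(
    Fp1 = sph(72, 108), Fp2 = sph(72, 72),
    F7 = sph(72, 144), F8 = sph(72, 36),
    T3 = sph(72, 180), T4 = sph(72, 0),
    T5 = sph(72, 216), T6 = sph(72, -36),
    O1 = sph(72, 252), O2 = sph(72, -72),
    Fz = sph(36, 90), Cz = c(0, 0, 1), Pz = sph(36, -90),
    C3 = sph(36, 180), C4 = sph(36, 0)
  )
  pos$F3 <- slerpMid(pos$Fz, pos$F7)
  pos$F4 <- slerpMid(pos$Fz, pos$F8)
  pos$P3 <- slerpMid(pos$Pz, pos$T5)
  pos$P4 <- slerpMid(pos$Pz, pos$T6)
  order <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
             "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  out <- do.call(rbind, pos[order]) * radius_mm
  rownames(out) <- order
  out
}

canonical1020Labels <- function() rownames(standard1020Positions())

# Map raw labels (case/synonym variants) onto canonical 10-20 names.
mapChannelLabels <- function(labels) {
  canon <- canonical1020Labels()
  syn <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  cleaned <- toupper(trimws(labels))
  lookup <- stats::setNames(canon, toupper(canon))
  lookup <- c(lookup, stats::setNames(unname(syn), names(syn)))
  mapped <- unname(lookup[cleaned])
  if (anyNA(mapped))
    stop("unmapped channel labels: ",
         paste(labels[is.na(mapped)], collapse = ", "))
  mapped
}

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelLabels channel names; mapped onto canonical 10-20 labels when
#'   \code{map = TRUE}.
#' @param reference referencing state.
#' @param map map labels onto canonical names (default TRUE).
#' @return An \linkS4class{EEGRecording}.
#' @export
eegRecording <- function(data, fs, channelLabels, reference = "original",
                         map = TRUE) {
  if (map) channelLabels <- mapChannelLabels(channelLabels)
  data <- as.matrix(data)
  dimnames(data) <- NULL                # labels live in channelLabels
  new("EEGRecording", data = data, fs = fs,
      channelLabels = channelLabels, reference = reference)
}

#' Read a scalp recording from EDF or delimited text
#'
#' Supported formats: classic EDF (16-bit, uniform sampling rate across
#' signals) and delimited text with a header row of channel labels (one column
#' per channel, one row per sample; sampling rate given by \code{fs} or an
#' \code{# fs: <Hz>} comment line).
#'
#' @param path file path.
#' @param format "edf", "csv", or "auto" (by extension).
#' @param fs sampling rate in Hz, required for delimited text without an fs
#'   comment line.
#' @return An \linkS4class{EEGRecording} with canonical labels and original
#'   reference.
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "edf", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") readEDF(path) else readDelimitedEEG(path, fs)
}

#' Write a recording to EDF or delimited text
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output path.
#' @param format "edf", "csv", or "auto" (by extension).
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") writeEDF(rec, path) else writeDelimitedEEG(rec, path)
  invisible(path)
}

readDelimitedEEG <- function(path, fs = NULL) {
  first <- readLines(path, n = 5)
  fsLine <- grep("^#\\s*fs:", first, value = TRUE)
  if (length(fsLine)) fs <- as.numeric(sub("^#\\s*fs:\\s*", "", fsLine[1]))
  if (is.null(fs) || !is.finite(fs))
    stop("sampling rate unknown: pass fs= or include an '# fs:' header line")
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  eegRecording(t(as.matrix(tab)), fs = fs, channelLabels = names(tab))
}

writeDelimitedEEG <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", rec@fs), con)
  tab <- as.data.frame(t(rec@data))
  names(tab) <- rec@channelLabels
  utils::write.csv(tab, con, row.names = FALSE)
}

# ---- classic EDF (16-bit) ---------------------------------------------------
# Minimal reader/writer for the classic European Data Format: fixed-layout
# ASCII header (256 bytes + 256 per signal) followed by little-endian int16
# data records. All signals are required to share one sampling rate.

padf <- function(x, width) formatC(as.character(x), width = width, flag = "-")

writeEDF <- function(rec, path) {
  x <- rec@data
  ns <- nrow(x)
  fs <- rec@fs
  # integer samples-per-record: use 1-second records
  spr <- as.integer(round(fs))
  if (abs(spr - fs) > 1e-9) stop("EDF writer requires an integer sampling rate")
  nrec <- floor(ncol(x) / spr)
  if (nrec < 1) stop("recording shorter than one EDF data record")
  x <- x[, seq_len(nrec * spr), drop = FALSE]
  physMin <- floor(apply(x, 1, min))
  physMax <- ceiling(apply(x, 1, max))
  physMax <- pmax(physMax, physMin + 1)
  digMin <- rep(-32768L, ns); digMax <- rep(32767L, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padf("0", 8), padf("X", 80), padf("X", 80),
    padf("01.01.00", 8), padf("00.00.00", 8),
    padf(256 * (ns + 1), 8), padf("", 44),
    padf(nrec, 8), padf(1, 8), padf(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, padf, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec@channelLabels, 16)          # label
  field(rep("", ns), 80)                # transducer
  field(rep("uV", ns), 8)               # physical dimension
  field(physMin, 8)
  field(physMax, 8)
  field(digMin, 8)
  field(digMax, 8)
  field(rep("", ns), 80)                # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                # reserved
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((x[s, idx] - physMin[s]) / scale[s]) + digMin[s]
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) readChar(con, nb, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  nbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("truncated or invalid EDF header")
  rdf <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- rdf(16); rdf(80); rdf(8)
  physMin <- as.numeric(rdf(8)); physMax <- as.numeric(rdf(8))
  digMin <- as.numeric(rdf(8)); digMax <- as.numeric(rdf(8))
  rdf(80)
  spr <- as.integer(rdf(8)); rdf(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader requires a single sampling rate across signals")
  fs <- spr[1] / dur
  x <- matrix(0, ns, nrec * spr[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[s]) stop("truncated EDF data record")
      x[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - digMin[s]) * scale[s] + physMin[s]
    }
  }
  eegRecording(x, fs = fs, channelLabels = labels)
}

# ---- preprocessing ----------------------------------------------------------

#' Common average reference
#'
#' Removes the instantaneous mean across channels from every sample. Guarded
#' against double application: re-referencing an already common-average
#' referenced recording is an error.
#'
#' @param rec an \linkS4class{EEGRecording} with original reference.
#' @return The re-referenced \linkS4class{EEGRecording}.
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@reference == "common_average")
    stop("recording is already common-average referenced")
  out <- rec
  out@data <- sweep(rec@data, 2, colMeans(rec@data))
  out@reference <- "common_average"
  validObject(out)
  out
}

#' Band-pass filter and resample a recording
#'
#' Reproduces the offline preprocessing chain: zero-phase band-pass to
#' [lo, hi] Hz followed by band-limited resampling to \code{fs_target}.
#' Upsampling is refused.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param lo,hi band edges in Hz (defaults 2 and 44).
#' @param fs_target output sampling rate in Hz (default 128).
#' @return The filtered, resampled \linkS4class{EEGRecording}.
#' @export
preprocessRecording <- function(rec, lo = 2, hi = 44, fs_target = 128) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@fs < 2 * hi)
    stop("sampling rate too low for the requested upper band edge")
  if (fs_target > rec@fs) stop("no upsampling: fs_target exceeds recording rate")
  y <- fftBandpass(t(rec@data), rec@fs, lo, hi)
  if (fs_target != rec@fs) y <- fftResample(y, rec@fs, fs_target)
  out <- rec
  out@data <- t(y)
  out@fs <- fs_target
  out
}

#' Epoch a recording and average Fourier cross-spectral matrices per band
#'
#' Cuts the recording into non-overlapping tapered epochs, discards epochs
#' whose peak absolute amplitude exceeds \code{amp_reject_uV} (an automated
#' stand-in for visual artifact rejection), computes the discrete Fourier
#' transform of each epoch, and averages the cross-spectral matrices over
#' epochs and over the Fourier bins inside each half-open band [lo, hi).
#' Per-epoch coefficients are retained for the phase-synchronization variant
#' of lagged coherence and for epoch-shuffling surrogates.
#'
#' @param rec a common-average referenced \linkS4class{EEGRecording}, or a
#'   plain channels x samples matrix of source-level series (rownames as
#'   labels; referencing does not apply in source space), with \code{fs}.
#' @param epoch_len_s epoch length in seconds (default 4: 0.25 Hz resolution,
#'   so the theta band spans >= 2 bins).
#' @param bands named list of band edges (default \code{defaultBands()}).
#' @param taper "hanning" or "none".
#' @param amp_reject_uV amplitude rejection threshold (default 100); use
#'   \code{Inf} to keep all epochs.
#' @param fs sampling rate, required when \code{rec} is a plain matrix.
#' @return A \linkS4class{BandCrossSpectra}.
#' @export
epochCrossSpectra <- function(rec, epoch_len_s = 4, bands = defaultBands(),
                              taper = c("hanning", "none"),
                              amp_reject_uV = 100, fs = NULL) {
  taper <- match.arg(taper)
  validateBands(bands)
  if (is(rec, "EEGRecording")) {
    if (rec@reference != "common_average")
      stop("cross-spectra require a common-average referenced recording")
    dat <- rec@data
    labs <- rec@channelLabels
    fs <- rec@fs
  } else {
    if (is.null(fs)) stop("fs is required for matrix input")
    dat <- as.matrix(rec)
    labs <- rownames(dat)
    if (is.null(labs)) labs <- sprintf("ch%02d", seq_len(nrow(dat)))
  }
  nper <- round(epoch_len_s * fs)
  nS <- ncol(dat)
  if (nper > nS) stop("epoch longer than the recording")
  nEp <- floor(nS / nper)
  if (nEp < 2) stop("need at least 2 epochs")
  w <- if (taper == "hanning") 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) else rep(1, nper)
  keepEp <- logical(nEp)
  coefAll <- array(0i, c(length(labs), nper, nEp))
  for (e in seq_len(nEp)) {
    seg <- dat[, ((e - 1) * nper + 1):(e * nper), drop = FALSE]
    keepEp[e] <- max(abs(seg)) <= amp_reject_uV
    if (keepEp[e])
      coefAll[, , e] <- t(stats::mvfft(t(seg * rep(w, each = nrow(seg))))) /
        sqrt(sum(w^2))
  }
  nKept <- sum(keepEp)
  if (nKept < 2)
    stop(sprintf("only %d epochs survive the %g uV amplitude threshold",
                 nKept, amp_reject_uV))
  coefAll <- coefAll[, , keepEp, drop = FALSE]
  f <- (seq_len(nper) - 1) / nper * fs
  S <- list(); coef <- list()
  for (b in names(bands)) {
    binIdx <- which(f >= bands[[b]][1] & f < bands[[b]][2] & f <= fs / 2)
    if (!length(binIdx)) stop("band '", b, "' contains no Fourier bins")
    cf <- coefAll[, binIdx, , drop = FALSE]
    Sb <- matrix(0i, dim(cf)[1], dim(cf)[1])
    for (e in seq_len(dim(cf)[3]))
      for (k in seq_len(dim(cf)[2]))
        Sb <- Sb + cf[, k, e] %*% Conj(t(cf[, k, e]))
    Sb <- Sb / (dim(cf)[2] * dim(cf)[3])
    S[[b]] <- (Sb + Conj(t(Sb))) / 2
    coef[[b]] <- cf
  }
  new("BandCrossSpectra", S = S, coef = coef, bands = bands,
      nEpochs = nKept, epochLen = epoch_len_s, taper = taper,
      channelLabels = labs, fs = fs)
}
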