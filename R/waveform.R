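#' Synthesize the sample-hold scan waveform for an exposure map
#'
#' Pixels are visited in row-major, unidirectional order, skipping zero-dwell
#' pixels. A visited pixel at (row m, col n), 0-based, contributes samples
#' held at voltages \code{(n*vs, m*vs)}: \code{f*E} samples when its
#' predecessor in scan order is its immediate left neighbour, and
#' \code{(f + beta*d)*E} samples otherwise, where \code{d} is the Chebyshev
#' distance to the previous visited pixel — the settling insertion that gives
#' the galvanometers time to traverse the gap. \code{E} is the dwell in
#' seconds; sample counts are rounded to the nearest integer, minimum 1. The
#' first visited pixel of a frame gets no settling. The dwell clock pulses at
#' each pixel's first sample and the line clock at each row's first visited
#' pixel; rows with no ROI pixels emit no line clock.
#'
#' @param exposureMap an [ExposureMap-class] or dwell matrix, us.
#' @param vs voltage step per pixel, V.
#' @param f output sampling rate, samples/s.
#' @param beta settling coefficient, samples/s per pixel of distance; the
#'   default \code{0.02 * f} balances scanner-lag compensation against
#'   imaging speed.
#' @param voltageLimit scanner input limit, V (+/- 3 V at 1 V per degree).
#' @param center if TRUE, offset voltages so mid-frame sits at 0 V.
#' @return a [ScanWaveform-class]; an all-zero exposure map gives a valid
#'   zero-length waveform.
#' @export
synthesizeWaveform <- function(exposureMap, vs = 0.01, f = 1e7,
                               beta = 0.02 * f, voltageLimit = 3,
                               center = FALSE) {
  E <- if (is(exposureMap, "ExposureMap")) exposureMap@E else exposureMap
  stopIfNot(is.matrix(E) && all(E >= 0), "exposure must be non-negative")
  stopIfNot(f > 0, "f must be > 0")
  stopIfNot(vs > 0, "vs must be > 0")
  h <- nrow(E); w <- ncol(E)
  emptyWf <- function() new("ScanWaveform", vx = numeric(0), vy = numeric(0),
    f = f, dwellClock = logical(0), lineClock = logical(0),
    pixelSpans = data.frame(row = integer(0), col = integer(0),
                            start = integer(0), n = integer(0),
                            settle = integer(0)),
    beta = beta, vs = vs)
  visited <- which(t(E) > 0)           # row-major order
  if (length(visited) == 0) return(emptyWf())
  m <- (visited - 1L) %/% w            # 0-based row
  n <- (visited - 1L) %% w             # 0-based col
  Esec <- t(E)[visited] * 1e-6

  pm <- c(NA, m[-length(m)])
  pn <- c(NA, n[-length(n)])
  leftAdj <- !is.na(pm) & pm == m & n - pn == 1
  d <- pmax(abs(m - pm), abs(n - pn))
  settleSamp <- ifelse(is.na(pm) | leftAdj, 0, beta * d * Esec)
  nsamp <- pmax(round(f * Esec + settleSamp), 1)
  nDwell <- pmax(round(f * Esec), 1)

  off <- if (center) c((w - 1) / 2, (h - 1) / 2) * vs else c(0, 0)
  vxPix <- n * vs - off[1]
  vyPix <- m * vs - off[2]
  if (max(abs(c(vxPix, vyPix))) > voltageLimit)
    stop("commanded voltage exceeds the +/-", voltageLimit, " V limit",
         call. = FALSE)
  total <- sum(nsamp)
  starts <- cumsum(c(1, nsamp[-length(nsamp)]))
  vx <- rep.int(vxPix, nsamp)
  vy <- rep.int(vyPix, nsamp)
  dwellClock <- logical(total); dwellClock[starts] <- TRUE
  lineClock <- logical(total)
  lineClock[starts[!duplicated(m)]] <- TRUE
  new("ScanWaveform", vx = vx, vy = vy, f = f, dwellClock = dwellClock,
      lineClock = lineClock,
      pixelSpans = data.frame(row = m, col = n, start = as.integer(starts),
                              n = as.integer(nsamp),
                              settle = as.integer(nsamp - nDwell)),
      beta = beta, vs = vs)
}

#' Uniform-exposure raster scan waveform
#'
#' Full-frame special case of [synthesizeWaveform()]: every pixel gets the
#' same dwell, and one settling insertion occurs at each row transition (the
#' flyback from a row's end to the next row's start is never left-adjacent).
#'
#' @param shape integer \code{c(height, width)}, pixels.
#' @param dwellUs per-pixel dwell, us (> 0).
#' @param vs,f,beta,voltageLimit,center as in [synthesizeWaveform()].
#' @return a [ScanWaveform-class].
#' @export
rasterWaveform <- function(shape, dwellUs, vs = 0.01, f = 1e7,
                           beta = 0.02 * f, voltageLimit = 3,
                           center = FALSE) {
  stopIfNot(dwellUs > 0, "dwell must be > 0")
  synthesizeWaveform(matrix(dwellUs, shape[1], shape[2]), vs = vs, f = f,
                     beta = beta, voltageLimit = voltageLimit,
                     center = center)
}

#' Smooth a scan waveform with a centred moving average
#'
#' Applies an odd-width boxcar (default 5 samples, the scanner-trajectory
#' refinement) to \code{vx} and \code{vy} independently; sequence ends are
#' padded by edge replication. Clocks and pixel spans are unchanged. At 1000
#' samples per pixel only a handful of samples around each voltage step are
#' altered, so scanning accuracy is essentially unaffected.
#'
#' @param w a [ScanWaveform-class].
#' @param window odd window length, samples.
#' @return the smoothed [ScanWaveform-class].
#' @export
smoothWaveform <- function(w, window = 5L) {
  stopIfNot(is(w, "ScanWaveform"), "w must be a ScanWaveform")
  stopIfNot(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  n <- length(w@vx)
  if (window == 1 || n == 0) return(w)
  if (window > n) stop("window larger than the waveform", call. = FALSE)
  half <- (window - 1L) / 2L
  boxcar <- function(x) {
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    cs <- cumsum(xp)
    (cs[(window):(n + window - 1)] - c(0, cs[1:(n - 1)])) / window
  }
  w@vx <- boxcar(w@vx)
  w@vy <- boxcar(w@vy)
  w
}

#' Predicted acquisition time of a waveform
#'
#' The frame time is the waveform length over the output rate — equivalently
#' the summed dwell plus settling samples, reflecting the total distance the
#' scanner travels.
#'
#' @param w a [ScanWaveform-class].
#' @return seconds.
#' @export
predictedFrameTime <- function(w) {
  stopIfNot(is(w, "ScanWaveform"), "w must be a ScanWaveform")
  length(w@vx) / w@f
}
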