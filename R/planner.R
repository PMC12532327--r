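#' Otsu threshold of an integer histogram
#'
#' Exhaustive maximization of the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} over all candidate split levels; a
#' threshold \eqn{t} separates the classes \eqn{\{levels \le t\}} and
#' \eqn{\{levels > t\}}. Ties are broken toward the lower level.
#'
#' @param histogram integer counts per gray level.
#' @param levels the gray-level values; defaults to \code{0:(n-1)}.
#' @return the threshold level (an element of \code{levels}).
#' @export
otsuThreshold <- function(histogram, levels = seq_along(histogram) - 1) {
  stopIfNot(length(histogram) == length(levels),
            "histogram and levels must have equal length")
  stopIfNot(all(histogram >= 0), "histogram counts must be >= 0")
  nz <- histogram > 0
  if (sum(nz) < 2)
    stop("histogram has fewer than 2 nonzero levels: no separation exists",
         call. = FALSE)
  p <- histogram / sum(histogram)
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  muT <- mu[length(mu)]
  w1 <- 1 - w0
  # candidates: all splits with mass on both sides
  ok <- w0 > 0 & w1 > 0
  sigmaB <- rep(-Inf, length(p))
  sigmaB[ok] <- (muT * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  levels[which.max(sigmaB)]   # which.max -> first (lowest) maximizer
}

# Background-aware Otsu: recursive (multi-level) descent accepting a split
# only once its lower class is dark-dominated. Returns NA when the histogram
# contains no dark-dominated class at all (pure-signal data).
otsuBackgroundSplit <- function(histogram, levels, darkFloor) {
  repeat {
    if (sum(histogram > 0) < 2) return(NA_real_)
    t <- otsuThreshold(histogram, levels)
    lower <- levels <= t
    muLow <- sum(histogram[lower] * levels[lower]) / sum(histogram[lower])
    if (muLow <= darkFloor) return(t)
    histogram <- histogram[lower]
    levels <- levels[lower]
  }
}

#' Per-pixel adaptive Otsu threshold map
#'
#' Splits the count map into square blocks, computes a per-block Otsu
#' threshold on each block's count histogram, and bilinearly interpolates the
#' block-centre thresholds to per-pixel values. Blocks whose counts collapse
#' to a single level inherit the global Otsu threshold; a globally
#' single-level image yields that level everywhere, with a warning.
#'
#' When \code{darkCounts} is supplied (the expected dark counts over the
#' pre-scan dwell), thresholds become background-aware: the Otsu split is
#' accepted only when its lower class is dark-dominated (class mean at most
#' \code{max(5 * darkCounts, 1)} counts); otherwise the split descends
#' recursively into the lower class — the standard multi-level Otsu descent —
#' so that a multi-modal count map (background, dim and bright species) is
#' thresholded between background and signal rather than between signal
#' classes. A block containing no background at all is pure signal and gets
#' threshold 0.
#'
#' @param counts pre-scan photon-count matrix.
#' @param block block side length in pixels (>= 8, <= the image size).
#' @param interpolate if FALSE, return the piecewise-constant per-block map
#'   (useful for checking block thresholds directly).
#' @param darkCounts expected dark counts over the pre-scan dwell, or NULL
#'   (default) for plain single-level Otsu per block.
#' @return numeric matrix of per-pixel thresholds.
#' @export
adaptiveOtsu <- function(counts, block = 32L, interpolate = TRUE,
                         darkCounts = NULL) {
  stopIfNot(is.matrix(counts) && all(counts >= 0),
            "counts must be a non-negative matrix")
  h <- nrow(counts); w <- ncol(counts)
  stopIfNot(block >= 8 && block <= max(h, w),
            "block must be >= 8 pixels and <= the image size")
  lv <- 0:max(counts)
  globalOk <- length(unique(as.vector(counts))) >= 2
  if (!globalOk) {
    warning("degenerate image with a single count level; thresholds equal it")
    return(matrix(counts[1], h, w))
  }
  blockThr <- if (is.null(darkCounts)) {
    function(hst) otsuThreshold(hst, lv)
  } else {
    darkFloor <- max(5 * darkCounts, 1)
    function(hst) {
      t <- otsuBackgroundSplit(hst, lv, darkFloor)
      if (is.na(t)) 0 else t
    }
  }
  globalThr <- blockThr(tabulate(as.vector(counts) + 1L, length(lv)))

  rStarts <- seq(1, h, by = block)
  cStarts <- seq(1, w, by = block)
  thr <- matrix(NA_real_, length(rStarts), length(cStarts))
  rCen <- cCen <- NULL
  for (i in seq_along(rStarts)) {
    ri <- rStarts[i]:min(rStarts[i] + block - 1, h)
    for (j in seq_along(cStarts)) {
      ci <- cStarts[j]:min(cStarts[j] + block - 1, w)
      blk <- counts[ri, ci]
      thr[i, j] <- if (length(unique(as.vector(blk))) >= 2)
        blockThr(tabulate(as.vector(blk) + 1L, length(lv)))
      else globalThr
    }
  }
  rCen <- vapply(seq_along(rStarts), function(i)
    mean(c(rStarts[i], min(rStarts[i] + block - 1, h))), numeric(1))
  cCen <- vapply(seq_along(cStarts), function(j)
    mean(c(cStarts[j], min(cStarts[j] + block - 1, w))), numeric(1))

  if (!interpolate) {
    out <- matrix(NA_real_, h, w)
    for (i in seq_along(rStarts)) for (j in seq_along(cStarts)) {
      ri <- rStarts[i]:min(rStarts[i] + block - 1, h)
      ci <- cStarts[j]:min(cStarts[j] + block - 1, w)
      out[ri, ci] <- thr[i, j]
    }
    return(out)
  }
  # separable bilinear interpolation of block centres, edge-extended
  interp1 <- function(centres, vals, at) {
    if (length(centres) == 1) return(rep(vals, length(at)))
    stats::approx(centres, vals, xout = at, rule = 2)$y
  }
  rowsInterp <- t(vapply(seq_len(nrow(thr)), function(i)
    interp1(cCen, thr[i, ], seq_len(w)), numeric(w)))
  out <- vapply(seq_len(w), function(j)
    interp1(rCen, rowsInterp[, j], seq_len(h)), numeric(h))
  matrix(out, h, w)
}

#' Classify pixels into non-ROI, dim and bright
#'
#' A pixel enters the ROI iff its pre-scan count strictly exceeds
#' \eqn{\alpha = \max(\mathrm{DCR}\cdot T_{prescan}, O_{thresh})}, the larger
#' of the expected dark counts over the pre-scan dwell and the (adaptive)
#' Otsu threshold. ROI pixels below the photon target are dim, the rest
#' bright.
#'
#' @param prescanCounts pre-scan count matrix.
#' @param dcr dark-count rate, counts/s (converted to expected counts over
#'   \code{tPrescanUs} before the max, for dimensional consistency).
#' @param tPrescanUs pre-scan dwell, us.
#' @param othresh per-pixel threshold matrix (from [adaptiveOtsu()]) or a
#'   scalar.
#' @param iTarget photon target separating dim from bright.
#' @return list with \code{roi} (logical matrix) and \code{classMap}
#'   (integer matrix: 0 non-ROI, 1 dim, 2 bright).
#' @export
classifyPixels <- function(prescanCounts, dcr, tPrescanUs, othresh, iTarget) {
  stopIfNot(is.matrix(prescanCounts), "prescanCounts must be a matrix")
  if (dcr < 0) stop("negative dcr", call. = FALSE)
  if (length(othresh) == 1)
    othresh <- matrix(othresh, nrow(prescanCounts), ncol(prescanCounts))
  stopIfNot(all(dim(othresh) == dim(prescanCounts)),
            "othresh shape must match prescanCounts")
  alpha <- pmax(dcr * tPrescanUs * 1e-6, othresh)
  roi <- prescanCounts > alpha
  cls <- matrix(0L, nrow(prescanCounts), ncol(prescanCounts))
  cls[roi] <- ifelse(prescanCounts[roi] < iTarget, 1L, 2L)
  list(roi = roi, classMap = cls)
}

#' Intensity inversion: pre-scan counts to adaptive exposure map
#'
#' Within the ROI, \eqn{E(m,n) = T_{baseline} I_{target} / P(m,n)}, clamped
#' to \code{[tMin, tMax]} and then rounded to the nearest multiple of
#' \code{step}; outside the ROI \eqn{E = 0}, so those pixels are skipped
#' entirely. Pixels whose pre-scan count equals the target keep the baseline
#' dwell (the fixed point of intensity inversion).
#'
#' @param prescanCounts pre-scan count matrix \eqn{P}.
#' @param roi logical ROI mask (from [classifyPixels()]).
#' @param iTarget photon target per pixel, > 0.
#' @param tBaseline baseline dwell, us.
#' @param tMin,tMax dwell caps, us.
#' @param step dwell quantization, us.
#' @param tPrescan pre-scan dwell recorded in the map (defaults to
#'   \code{tBaseline}).
#' @param classMap optional class map to carry through; recomputed from
#'   \code{roi} and \code{iTarget} if missing.
#' @return an [ExposureMap-class].
#' @export
computeExposureMap <- function(prescanCounts, roi, iTarget, tBaseline,
                               tMin = 50, tMax = 600, step = 1,
                               tPrescan = tBaseline, classMap = NULL) {
  stopIfNot(iTarget > 0, "iTarget must be > 0")
  stopIfNot(tMin <= tMax, "tMin must be <= tMax")
  stopIfNot(step > 0, "step must be > 0")
  stopIfNot(is.matrix(prescanCounts) && all(dim(roi) == dim(prescanCounts)),
            "roi shape must match prescanCounts")
  P <- prescanCounts
  if (any(roi & P <= 0))
    stop("internal error: zero pre-scan count inside the ROI", call. = FALSE)
  E <- matrix(0, nrow(P), ncol(P))
  raw <- tBaseline * iTarget / P[roi]
  clamped <- pmin(pmax(raw, tMin), tMax)
  q <- round(clamped / step) * step
  # keep quantized dwells inside the caps even for coarse steps
  q <- pmin(pmax(q, ceiling(tMin / step - 1e-9) * step),
            floor(tMax / step + 1e-9) * step)
  E[roi] <- q
  if (is.null(classMap)) {
    classMap <- matrix(0L, nrow(P), ncol(P))
    classMap[roi] <- ifelse(P[roi] < iTarget, 1L, 2L)
  }
  new("ExposureMap", E = E, roi = roi, classMap = classMap,
      tBaseline = tBaseline, tPrescan = tPrescan, iTarget = iTarget,
      tMin = tMin, tMax = tMax, step = step)
}

#' Plan an adaptive exposure map from a pre-scan
#'
#' Convenience chain: adaptive Otsu thresholds, dark-count/threshold pixel
#' classification, intensity inversion with caps and quantization.
#'
#' @param prescan an [AcquisitionResult-class] of a uniform pre-scan, or a
#'   count matrix.
#' @param dcr dark-count rate, counts/s.
#' @param tPrescan pre-scan dwell, us (taken from the acquisition's exposure
#'   map when omitted).
#' @param iTarget photon target per pixel.
#' @param tBaseline baseline dwell, us; defaults to \code{tPrescan}.
#' @param tMin,tMax,step caps and quantization, us.
#' @param block adaptive-Otsu block size, pixels.
#' @param roiMode \code{"auto"} (threshold-based classification) or
#'   \code{"all"} (full-frame ROI; no pixels skipped).
#' @return an [ExposureMap-class].
#' @export
planExposure <- function(prescan, dcr = 100, tPrescan = NULL, iTarget = 250,
                         tBaseline = NULL, tMin = 50, tMax = 600, step = 1,
                         block = 32L, roiMode = c("auto", "all")) {
  roiMode <- match.arg(roiMode)
  counts <- if (is(prescan, "AcquisitionResult")) prescan@counts else prescan
  if (is.null(tPrescan)) {
    stopIfNot(is(prescan, "AcquisitionResult"),
              "tPrescan needed when prescan is a plain matrix")
    nz <- prescan@exposureUsed[prescan@exposureUsed > 0]
    tPrescan <- if (length(nz)) nz[1] else 0
  }
  if (is.null(tBaseline)) tBaseline <- tPrescan
  if (roiMode == "all") {
    roi <- matrix(TRUE, nrow(counts), ncol(counts))
    if (any(counts <= 0))
      stop("roiMode 'all' requires positive pre-scan counts everywhere",
           call. = FALSE)
    cls <- matrix(ifelse(counts < iTarget, 1L, 2L), nrow(counts), ncol(counts))
  } else {
    thr <- adaptiveOtsu(counts, block = block,
                        darkCounts = dcr * tPrescan * 1e-6)
    cl <- classifyPixels(counts, dcr, tPrescan, thr, iTarget)
    roi <- cl$roi; cls <- cl$classMap
    if (!any(roi)) warning("empty ROI: pre-scan is all dark")
  }
  computeExposureMap(counts, roi, iTarget, tBaseline, tMin, tMax, step,
                     tPrescan = tPrescan, classMap = cls)
}

#' Pixels whose dwell was not clamped at either cap
#'
#' @param em an [ExposureMap-class].
#' @return logical matrix: TRUE for ROI pixels with
#'   \code{tMin < E < tMax}.
#' @export
uncappedMask <- function(em) {
  stopIfNot(is(em, "ExposureMap"), "em must be an ExposureMap")
  em@roi & em@E > em@tMin & em@E < em@tMax
}
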