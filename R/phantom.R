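#' Generate a two-species heterogeneous phantom
#'
#' Builds the standard virtual specimen the adaptive planner targets: a
#' spatially contiguous \emph{bright, short-lifetime} species embedded in a
#' \emph{dim, long-lifetime} species, on an empty (zero-rate) background.
#' This anti-correlation of intensity and lifetime is the regime in which
#' uniform-exposure FLIM loses the long-lifetime species, because the photon
#' budget is set by the bright pixels.
#'
#' Default rates are calibrated so that a 100 us dwell yields mean expected
#' counts of 871 over the bright region and 117 over the dim region. A seeded
#' smooth intensity gradient modulates each region multiplicatively
#' (\code{dimSpread}, \code{brightSpread} giving relative half-ranges) and is
#' renormalized so the \emph{region means are exact}.
#'
#' @param shape integer vector \code{c(height, width)} in pixels.
#' @param brightRate,dimRate mean emission rates, detected photons/us;
#'   \code{brightRate > dimRate >= 0}.
#' @param tauBright,tauDim species lifetimes, ns.
#' @param geometry list describing the parametric layout. \code{type="blobs"}
#'   (the default): a large dim disk covering \code{dimFraction} of the frame
#'   with \code{nBlobs} bright disks of total area \code{brightFraction}
#'   placed inside it. \code{type="bands"}: horizontal dim band with a bright
#'   band inside.
#' @param dimSpread,brightSpread relative half-range of the within-region
#'   intensity gradient, e.g. 0.5 spans 0.5x-1.5x the region mean.
#' @param dcr detector dark-count rate, counts/s.
#' @param seed integer seed; identical seeds give bit-identical samples.
#' @return a [SampleModel-class].
#' @examples
#' ph <- twoSpeciesPhantom(c(64, 64), seed = 1)
#' mean(rateMap(ph)[tauMap(ph) == 0.8 & rateMap(ph) > 0]) * 100  # 871
#' @export
twoSpeciesPhantom <- function(shape = c(128, 128), brightRate = 8.71,
                              dimRate = 1.17, tauBright = 0.8, tauDim = 2.5,
                              geometry = list(type = "blobs"),
                              dimSpread = 0.6, brightSpread = 0.05,
                              dcr = 100, seed = 1L) {
  stopIfNot(length(shape) == 2 && all(shape >= 4) &&
              all(shape == round(shape)), "shape must be two pixel counts >= 4")
  stopIfNot(brightRate > dimRate && dimRate >= 0,
            "need brightRate > dimRate >= 0")
  stopIfNot(tauBright > 0 && tauDim > 0, "lifetimes must be positive")
  stopIfNot(dimSpread >= 0 && dimSpread < 1 && brightSpread >= 0 &&
              brightSpread < 1, "spreads must lie in [0, 1)")
  h <- shape[1]; w <- shape[2]
  geom <- utils::modifyList(
    list(type = "blobs", nBlobs = 5, dimFraction = 0.45,
         brightFraction = 0.12), geometry)

  withSeed(seed, {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    if (geom$type == "blobs") {
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      rDim <- sqrt(geom$dimFraction * h * w / pi)
      dimMask <- (rows - cy)^2 + (cols - cx)^2 <= rDim^2
      brightMask <- matrix(FALSE, h, w)
      rB <- sqrt(geom$brightFraction * h * w / (pi * geom$nBlobs))
      for (k in seq_len(geom$nBlobs)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, max(rDim - rB - 1, 0))
        by <- cy + rad * sin(ang); bx <- cx + rad * cos(ang)
        brightMask <- brightMask | ((rows - by)^2 + (cols - bx)^2 <= rB^2)
      }
      brightMask <- brightMask & dimMask
      dimMask <- dimMask & !brightMask
    } else if (geom$type == "bands") {
      dimMask <- rows > h * 0.2 & rows <= h * 0.8
      brightMask <- rows > h * 0.45 & rows <= h * 0.65
      dimMask <- dimMask & !brightMask
    } else stop("unknown geometry type: ", geom$type, call. = FALSE)

    # smooth seeded gradient spanning +/- spread within each region, then
    # renormalized so the region mean is exact
    ang <- stats::runif(1, 0, 2 * pi)
    proj <- (rows / h) * sin(ang) + (cols / w) * cos(ang)
    regionField <- function(mask, spread) {
      p <- proj[mask]
      rng <- max(p) - min(p)
      u <- if (rng > 0) (p - min(p)) / rng else rep(0.5, length(p))
      g <- 1 + spread * (2 * u - 1)
      g / mean(g)
    }
    rate <- matrix(0, h, w)
    if (dimRate > 0 && any(dimMask))
      rate[dimMask] <- dimRate * regionField(dimMask, dimSpread)
    if (any(brightMask))
      rate[brightMask] <- brightRate * regionField(brightMask, brightSpread)
    tau <- matrix(0, h, w)
    tau[dimMask] <- tauDim
    tau[brightMask] <- tauBright
    new("SampleModel", rate = rate, tau = tau, dcr = dcr,
        excitationScale = 1)
  })
}

#' Import a grayscale image as a phantom rate map
#'
#' Normalizes a non-negative image to \code{[0, peakRate]} detected photons/us
#' and assigns lifetimes by a mapping spec. The default \code{"inverse"}
#' mapping reproduces the anti-correlated regime (bright pixels short-lived):
#' \code{tau = tauMax - (tauMax - tauMin) * image/max(image)}.
#'
#' @param image numeric matrix, non-negative, not all zero.
#' @param peakRate rate assigned to the image maximum, photons/us.
#' @param tauSpec list: \code{type} one of \code{"inverse"} (intensity ramp
#'   from \code{tauMax} down to \code{tauMin}) or \code{"constant"}
#'   (\code{tau} everywhere); plus the named lifetime parameters in ns.
#' @param dcr detector dark-count rate, counts/s.
#' @return a [SampleModel-class].
#' @export
phantomFromImage <- function(image, peakRate,
                             tauSpec = list(type = "inverse", tauMin = 0.8,
                                            tauMax = 2.5),
                             dcr = 100) {
  stopIfNot(is.matrix(image) && all(is.finite(image)) && all(image >= 0),
            "image must be a finite non-negative matrix")
  stopIfNot(peakRate > 0, "peakRate must be > 0")
  mx <- max(image)
  if (mx == 0) stop("all-zero image: no normalization possible", call. = FALSE)
  rel <- image / mx
  rate <- rel * peakRate
  tau <- matrix(0, nrow(image), ncol(image))
  on <- rate > 0
  if (identical(tauSpec$type, "inverse")) {
    tau[on] <- tauSpec$tauMax - (tauSpec$tauMax - tauSpec$tauMin) * rel[on]
  } else if (identical(tauSpec$type, "constant")) {
    tau[on] <- tauSpec$tau
  } else stop("unknown tauSpec type: ", tauSpec$type, call. = FALSE)
  new("SampleModel", rate = rate, tau = tau, dcr = dcr, excitationScale = 1)
}

#' Scale the excitation power of a sample
#'
#' Multiplies the sample's excitation scale; expected signal counts at any
#' dwell scale linearly with it (pre-saturation regime).
#'
#' @param sample a [SampleModel-class].
#' @param factor positive multiplier.
#' @return the rescaled [SampleModel-class].
#' @export
scaleExcitation <- function(sample, factor) {
  stopIfNot(is(sample, "SampleModel"), "sample must be a SampleModel")
  stopIfNot(is.numeric(factor) && length(factor) == 1 && factor > 0,
            "factor must be a single positive number")
  sample@excitationScale <- sample@excitationScale * factor
  validObject(sample)
  sample
}
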