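#' TCSPC acquisition parameters
#'
#' Constructor with desk-scale defaults: 20 MHz repetition rate (50 ns
#' window), 100 ps bins (500 bins), 40 ps IRF sigma and a 0.55 ns decay
#' origin. The origin default sits at a bin centre at the default binning,
#' which is the convention the centre-of-mass estimator assumes.
#'
#' @param repRate laser repetition rate, Hz.
#' @param binWidthPs TCSPC bin width, ps (>= 10).
#' @param irfSigmaPs IRF Gaussian sigma, ps.
#' @param t0Ns decay origin (detection-path delay), ns.
#' @param windowBins number of bins; default \code{floor(period/binWidth)}.
#' @param maxDwellUs guard against runaway exposure maps, us.
#' @return an [AcqParams-class].
#' @export
acqParams <- function(repRate = 20e6, binWidthPs = 100, irfSigmaPs = 40,
                      t0Ns = 0.55, windowBins = NULL, maxDwellUs = 1e4) {
  periodNs <- 1e9 / repRate
  if (is.null(windowBins))
    windowBins <- floor(periodNs * 1000 / binWidthPs)
  new("AcqParams", repRate = repRate, binWidthPs = binWidthPs,
      irfSigmaPs = irfSigmaPs, t0Ns = t0Ns,
      windowBins = as.integer(windowBins), maxDwellUs = maxDwellUs)
}

windowNs <- function(params) params@windowBins * params@binWidthPs / 1000

#' Simulate one TCSPC scan of a virtual sample
#'
#' Photon-budget model: at dwell \eqn{E} us the signal count is
#' Poisson(\code{rate * excitationScale * E}) and the dark count is
#' Poisson(\code{dcr * E}). Each signal photon's arrival time is drawn from
#' the pixel's exponential (or rate-weighted bi-exponential) decay, offset by
#' the decay origin, jittered by the Gaussian IRF, and wrapped modulo the
#' binned window (incomplete-decay wrap at the laser period); dark photons are
#' uniform over the window. Counts scale linearly with dwell and with the
#' excitation scale, and \code{sd/mean} of replicate counts follows the
#' Poisson shot-noise law \eqn{1/\sqrt{N}}.
#'
#' @param sample a [SampleModel-class].
#' @param exposureMap an [ExposureMap-class] or a numeric dwell matrix (us)
#'   of the sample's shape; 0 marks skipped pixels.
#' @param params an [AcqParams-class].
#' @param seed integer seed; identical seeds give identical results.
#' @param recordHist if FALSE, only per-pixel counts are recorded (faster and
#'   lighter; no lifetime estimation possible downstream).
#' @param frameTime predicted frame time (s) to store with the result;
#'   defaults to the summed dwell. Pass [predictedFrameTime()] of the scan
#'   waveform for the settling-aware figure.
#' @return an [AcquisitionResult-class].
#' @export
simulateAcquisition <- function(sample, exposureMap, params = acqParams(),
                                seed = 1L, recordHist = TRUE,
                                frameTime = NULL) {
  stopIfNot(is(sample, "SampleModel"), "sample must be a SampleModel")
  E <- if (is(exposureMap, "ExposureMap")) exposureMap@E else exposureMap
  stopIfNot(is.matrix(E) && all(dim(E) == dim(sample@rate)),
            "sample and exposure shapes must match")
  stopIfNot(all(E >= 0), "dwell times must be >= 0")
  if (any(E > params@maxDwellUs))
    stop("dwell exceeds the configured maximum of ", params@maxDwellUs,
         " us", call. = FALSE)
  h <- nrow(E); w <- ncol(E); npix <- h * w
  B <- params@windowBins
  winNs <- windowNs(params)
  lamSig <- as.vector(sample@rate) * sample@excitationScale * as.vector(E)
  lamDark <- sample@dcr * 1e-6 * as.vector(E)

  res <- withSeed(seed, {
    nSig <- stats::rpois(npix, lamSig)
    nDark <- stats::rpois(npix, lamDark)
    counts <- nSig + nDark
    histArr <- array(numeric(0), c(0, 0, 0))
    if (recordHist) {
      pixS <- rep.int(seq_len(npix), nSig)
      tauPh <- rep.int(as.vector(sample@tau), nSig)
      if (length(sample@frac2) > 0) {
        p2 <- rep.int(as.vector(sample@frac2), nSig)
        tau2Ph <- rep.int(as.vector(sample@tau2), nSig)
        useB <- stats::runif(length(pixS)) < p2
        tauPh[useB] <- tau2Ph[useB]
      }
      tSig <- params@t0Ns + stats::rexp(length(pixS)) * tauPh
      if (params@irfSigmaPs > 0)
        tSig <- tSig + stats::rnorm(length(pixS), 0,
                                    params@irfSigmaPs / 1000)
      tSig <- tSig %% winNs
      pixD <- rep.int(seq_len(npix), nDark)
      tDark <- stats::runif(length(pixD)) * winNs
      pix <- c(pixS, pixD)
      bin <- pmin(floor(c(tSig, tDark) * 1000 / params@binWidthPs) + 1, B)
      acc <- tabulate((pix - 1L) * B + bin, nbins = npix * B)
      # acc is bin-major within pixel; reshape to h x w x B
      histArr <- aperm(array(acc, c(B, h, w)), c(2, 3, 1))
    }
    list(counts = matrix(counts, h, w), hist = histArr)
  })
  new("AcquisitionResult", counts = res$counts, hist = res$hist,
      binWidthPs = params@binWidthPs, exposureUsed = E,
      seed = as.integer(seed),
      predictedTime = if (is.null(frameTime)) sum(E) * 1e-6 else frameTime)
}

#' Merge two acquisitions of the same scene
#'
#' Adds counts and decay histograms pixel-wise and bin-wise, the mechanism by
#' which pre-scan photon timing is reused during adaptive imaging without time
#' redundancy: merging a pre-scan with an adaptive scan is statistically
#' identical to a single scan at the summed dwell (Poisson additivity).
#' Exposure maps and predicted frame times add.
#'
#' @param a,b [AcquisitionResult-class] objects with identical shape and
#'   binning.
#' @return the merged [AcquisitionResult-class].
#' @export
mergeAcquisitions <- function(a, b) {
  stopIfNot(is(a, "AcquisitionResult") && is(b, "AcquisitionResult"),
            "both arguments must be AcquisitionResult objects")
  if (!all(dim(a@counts) == dim(b@counts)))
    stop("shape mismatch between acquisitions", call. = FALSE)
  if (a@binWidthPs != b@binWidthPs ||
      (length(a@hist) > 0 && length(b@hist) > 0 &&
       !all(dim(a@hist) == dim(b@hist))))
    stop("binning mismatch between acquisitions", call. = FALSE)
  hist <- if (length(a@hist) && length(b@hist)) a@hist + b@hist
          else array(numeric(0), c(0, 0, 0))
  new("AcquisitionResult", counts = a@counts + b@counts, hist = hist,
      binWidthPs = a@binWidthPs, exposureUsed = a@exposureUsed + b@exposureUsed,
      seed = a@seed, predictedTime = a@predictedTime + b@predictedTime)
}
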