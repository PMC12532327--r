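#' @import methods
NULL

.emptyMat <- matrix(numeric(0), 0, 0)

#' Virtual sample: per-pixel emission-rate and lifetime maps
#'
#' A \code{SampleModel} is the ground truth the virtual microscope images: an
#' emission-rate map (detected photons per microsecond of dwell at the
#' reference excitation power, detection efficiency folded in), a lifetime map
#' (ns), an optional second decay component, a scalar detector dark-count rate
#' and a dimensionless excitation scale. Expected signal counts at dwell
#' \eqn{E} (us) are \code{rate * excitationScale * E}.
#'
#' @slot rate numeric matrix, detected photons/us per pixel; non-negative.
#' @slot tau numeric matrix, ns; positive wherever \code{rate > 0}.
#' @slot tau2 numeric matrix, ns; second-component lifetime, or a 0x0 matrix
#'   for mono-exponential samples.
#' @slot frac2 numeric matrix in [0,1]; photon fraction of the second
#'   component, or a 0x0 matrix.
#' @slot dcr numeric scalar, detector dark counts per second.
#' @slot excitationScale numeric scalar > 0, multiplier on \code{rate}.
#'
#' @seealso [twoSpeciesPhantom()], [phantomFromImage()], [scaleExcitation()]
#' @exportClass SampleModel
setClass("SampleModel",
  representation(rate = "matrix", tau = "matrix", tau2 = "matrix",
                 frac2 = "matrix", dcr = "numeric",
                 excitationScale = "numeric"),
  prototype(rate = .emptyMat, tau = .emptyMat, tau2 = .emptyMat,
            frac2 = .emptyMat, dcr = 100, excitationScale = 1))

setValidity("SampleModel", function(object) {
  msg <- character(0)
  if (any(object@rate < 0)) msg <- c(msg, "rate must be >= 0 everywhere")
  if (!all(dim(object@rate) == dim(object@tau)))
    msg <- c(msg, "rate and tau must have identical dimensions")
  on <- object@rate > 0
  if (any(on) && any(object@tau[on] <= 0))
    msg <- c(msg, "tau must be > 0 wherever rate > 0")
  if (length(object@frac2) > 0) {
    if (!all(dim(object@frac2) == dim(object@rate)) ||
        !all(dim(object@tau2) == dim(object@rate)))
      msg <- c(msg, "tau2/frac2 must match rate dimensions when present")
    else {
      if (any(object@frac2 < 0 | object@frac2 > 1))
        msg <- c(msg, "frac2 must lie in [0,1]")
      bi <- on & object@frac2 > 0
      if (any(bi) && any(object@tau2[bi] <= 0))
        msg <- c(msg, "tau2 must be > 0 wherever frac2 > 0 and rate > 0")
    }
  }
  if (length(object@dcr) != 1 || object@dcr < 0)
    msg <- c(msg, "dcr must be a single non-negative number")
  if (length(object@excitationScale) != 1 || object@excitationScale <= 0)
    msg <- c(msg, "excitationScale must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' TCSPC acquisition parameters
#'
#' Timing parameters of the virtual TCSPC detection chain. The laser period is
#' \code{1e9 / repRate} ns; the decay window holds
#' \code{windowBins = floor(period / binWidth)} bins. A fixed excitation
#' offset \code{t0Ns} (detection-path delay) places the decay rise away from
#' the window edge; photon arrival times are wrapped modulo the binned window
#' so late tail photons re-enter at the front (incomplete-decay wrap).
#'
#' @slot repRate laser pulse repetition rate, Hz.
#' @slot binWidthPs TCSPC bin width, ps (>= 10 ps, the hardware floor).
#' @slot irfSigmaPs Gaussian instrument-response sigma, ps.
#' @slot t0Ns excitation/detection delay placing the decay origin, ns.
#' @slot windowBins number of histogram bins.
#' @slot maxDwellUs guard on per-pixel dwell, us.
#'
#' @seealso [acqParams()]
#' @exportClass AcqParams
setClass("AcqParams",
  representation(repRate = "numeric", binWidthPs = "numeric",
                 irfSigmaPs = "numeric", t0Ns = "numeric",
                 windowBins = "integer", maxDwellUs = "numeric"))

setValidity("AcqParams", function(object) {
  msg <- character(0)
  if (object@repRate <= 0) msg <- c(msg, "repRate must be > 0")
  if (object@binWidthPs < 10)
    msg <- c(msg, "binWidthPs must be >= 10 ps")
  periodNs <- 1e9 / object@repRate
  if (object@windowBins < 1) msg <- c(msg, "windowBins must be >= 1")
  if (object@windowBins * object@binWidthPs / 1000 > periodNs + 1e-9)
    msg <- c(msg, "windowBins * binWidthPs must not exceed the laser period")
  if (object@irfSigmaPs < 0) msg <- c(msg, "irfSigmaPs must be >= 0")
  if (object@t0Ns < 0 || object@t0Ns >= periodNs)
    msg <- c(msg, "t0Ns must lie in [0, laser period)")
  if (object@maxDwellUs <= 0) msg <- c(msg, "maxDwellUs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Adaptive per-pixel exposure map
#'
#' Per-pixel dwell times (us) produced by intensity inversion of a pre-scan.
#' \code{E == 0} marks skipped pixels (exactly the complement of \code{roi});
#' nonzero dwells lie in \code{[tMin, tMax]} and are integer multiples of
#' \code{step}. \code{classMap} labels pixels 0 = non-ROI, 1 = dim
#' (pre-scan counts below the photon target), 2 = bright.
#'
#' @slot E numeric matrix, dwell per pixel, us.
#' @slot roi logical matrix, TRUE where the pixel is imaged.
#' @slot classMap integer matrix in \{0, 1, 2\}.
#' @slot tBaseline,tPrescan baseline / pre-scan dwell, us.
#' @slot iTarget photon target per pixel.
#' @slot tMin,tMax dwell caps, us.
#' @slot step dwell quantization, us.
#'
#' @seealso [computeExposureMap()], [planExposure()]
#' @exportClass ExposureMap
setClass("ExposureMap",
  representation(E = "matrix", roi = "matrix", classMap = "matrix",
                 tBaseline = "numeric", tPrescan = "numeric",
                 iTarget = "numeric", tMin = "numeric", tMax = "numeric",
                 step = "numeric"))

setValidity("ExposureMap", function(object) {
  msg <- character(0)
  E <- object@E; roi <- object@roi
  if (!is.logical(roi) || !all(dim(roi) == dim(E)))
    msg <- c(msg, "roi must be a logical matrix matching E")
  if (!all(dim(object@classMap) == dim(E)))
    msg <- c(msg, "classMap must match E dimensions")
  if (any(E[!roi] != 0)) msg <- c(msg, "E must be 0 outside the roi")
  nz <- E[roi]
  if (length(nz)) {
    if (any(nz < object@tMin - 1e-9 | nz > object@tMax + 1e-9))
      msg <- c(msg, "nonzero E must lie within [tMin, tMax]")
    if (any(abs(nz / object@step - round(nz / object@step)) > 1e-6))
      msg <- c(msg, "nonzero E must be integer multiples of step")
  }
  if (any((object@classMap == 0L) != !roi))
    msg <- c(msg, "classMap must be 0 exactly where roi is FALSE")
  if (object@tMin > object@tMax) msg <- c(msg, "tMin must be <= tMax")
  if (object@step <= 0) msg <- c(msg, "step must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of one simulated TCSPC scan
#'
#' Per-pixel total photon counts and, unless histogram recording was turned
#' off, the per-pixel decay histograms as an \code{height x width x bins}
#' integer array. \code{sum(hist[m, n, ]) == counts[m, n]} always holds when
#' histograms are recorded.
#'
#' @slot counts numeric matrix of detected photons per pixel.
#' @slot hist numeric array (h x w x bins), or a 0-length array when the scan
#'   was run counts-only.
#' @slot binWidthPs bin width the histograms were recorded at, ps.
#' @slot exposureUsed numeric matrix, the dwell map applied, us.
#' @slot seed integer seed the scan was drawn with.
#' @slot predictedTime predicted frame time, s.
#'
#' @seealso [simulateAcquisition()], [mergeAcquisitions()]
#' @exportClass AcquisitionResult
setClass("AcquisitionResult",
  representation(counts = "matrix", hist = "array", binWidthPs = "numeric",
                 exposureUsed = "matrix", seed = "integer",
                 predictedTime = "numeric"))

setValidity("AcquisitionResult", function(object) {
  msg <- character(0)
  if (!all(dim(object@counts) == dim(object@exposureUsed)))
    msg <- c(msg, "counts and exposureUsed must have identical dimensions")
  if (length(object@hist) > 0) {
    d <- dim(object@hist)
    if (length(d) != 3 || !all(d[1:2] == dim(object@counts)))
      msg <- c(msg, "hist must be a h x w x bins array matching counts")
    else if (max(abs(rowSums(matrix(object@hist, prod(d[1:2]), d[3])) -
                     as.vector(object@counts))) > 1e-9)
      msg <- c(msg, "sum over histogram bins must equal counts at every pixel")
  }
  if (any(object@counts[object@exposureUsed == 0] != 0))
    msg <- c(msg, "counts must be 0 wherever exposure is 0")
  if (length(msg)) msg else TRUE
})

#' Sample-hold galvanometer scan waveform
#'
#' X/Y voltage sequences at a fixed output rate \code{f}, with embedded dwell
#' and line clocks and a pixel-to-sample index map. Settling samples (held at
#' the target voltage) are inserted when the scanner jumps between pixels that
#' are not left-adjacent in scan order.
#'
#' @slot vx,vy voltage sample sequences, V.
#' @slot f output sampling rate, samples/s.
#' @slot dwellClock,lineClock logical marker sequences aligned to \code{vx}.
#' @slot pixelSpans data.frame with columns \code{row}, \code{col},
#'   \code{start}, \code{n}, \code{settle} (0-based pixel coordinates,
#'   1-based first sample index, total samples, settling samples included in
#'   \code{n}).
#' @slot beta settling coefficient, samples/s per pixel of Chebyshev distance.
#' @slot vs voltage step per pixel, V.
#'
#' @seealso [synthesizeWaveform()], [rasterWaveform()], [smoothWaveform()]
#' @exportClass ScanWaveform
setClass("ScanWaveform",
  representation(vx = "numeric", vy = "numeric", f = "numeric",
                 dwellClock = "logical", lineClock = "logical",
                 pixelSpans = "data.frame", beta = "numeric", vs = "numeric"))

setValidity("ScanWaveform", function(object) {
  msg <- character(0)
  n <- length(object@vx)
  if (length(object@vy) != n || length(object@dwellClock) != n ||
      length(object@lineClock) != n)
    msg <- c(msg, "vx, vy, dwellClock, lineClock must have equal length")
  ps <- object@pixelSpans
  if (nrow(ps)) {
    if (ps$start[1] != 1 || sum(ps$n) != n ||
        any(ps$start != cumsum(c(1, ps$n[-nrow(ps)]))))
      msg <- c(msg, "pixelSpans must be ordered, disjoint and cover all samples")
  } else if (n != 0) msg <- c(msg, "non-empty waveform needs pixelSpans")
  if (object@f <= 0) msg <- c(msg, "f must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-pixel lifetime image
#'
#' Lifetime estimates with a validity mask. \code{tauHat} is finite and
#' positive exactly where \code{valid} is TRUE (NA elsewhere); \code{fitError}
#' holds the normalized fit error — the reduced chi-square of the
#' least-squares fit divided by the pixel's photon count — where that
#' estimator ran (NA otherwise).
#'
#' @slot tauHat numeric matrix, ns.
#' @slot valid logical matrix.
#' @slot fitError numeric matrix, dimensionless.
#' @slot counts numeric matrix, photons used per pixel.
#'
#' @seealso [lifetimeImage()], [lifetimeAvailability()]
#' @exportClass LifetimeImage
setClass("LifetimeImage",
  representation(tauHat = "matrix", valid = "matrix", fitError = "matrix",
                 counts = "matrix"))

setValidity("LifetimeImage", function(object) {
  msg <- character(0)
  d <- dim(object@tauHat)
  if (!all(dim(object@valid) == d) || !all(dim(object@fitError) == d) ||
      !all(dim(object@counts) == d))
    msg <- c(msg, "all slots must share one dimension")
  v <- object@valid
  th <- object@tauHat
  if (any(v & (!is.finite(th) | th <= 0)))
    msg <- c(msg, "tauHat must be finite and > 0 where valid")
  if (any(!v & is.finite(th)))
    msg <- c(msg, "tauHat must be NA where invalid")
  if (length(msg)) msg else TRUE
})

#' Report of a dual-mode imaging experiment
#'
#' Per-arm acquisition metrics (frame time, ROI count-histogram statistics,
#' lifetime availability, dim/bright-region fit errors) plus the derived
#' deltas: signal enhancement at equal time, speedup at equal SNR and
#' availability gain.
#'
#' @slot arms data.frame, one row per imaging arm.
#' @slot deltas named numeric vector of percentage deltas.
#' @slot config the experiment configuration used.
#'
#' @seealso [runExperimentSuite()]
#' @exportClass ExperimentReport
setClass("ExperimentReport",
  representation(arms = "data.frame", deltas = "numeric", config = "list"))
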