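#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: \code{rateMap}
#' and \code{tauMap} (SampleModel ground truth), \code{photonCounts} and
#' \code{decayHist} (AcquisitionResult), \code{exposure}, \code{roiMask} and
#' \code{classMap} (ExposureMap), \code{tauHat}, \code{validMask} and
#' \code{fitError} (LifetimeImage).
#'
#' @param object an object of the matching class.
#' @return the matrix/array stored in the corresponding slot.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("rateMap", function(object) standardGeneric("rateMap"))

#' @rdname accessors
#' @export
setGeneric("tauMap", function(object) standardGeneric("tauMap"))

#' @rdname accessors
#' @export
setGeneric("photonCounts", function(object) standardGeneric("photonCounts"))

#' @rdname accessors
#' @export
setGeneric("decayHist", function(object) standardGeneric("decayHist"))

#' @rdname accessors
#' @export
setGeneric("exposure", function(object) standardGeneric("exposure"))

#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setGeneric("classMap", function(object) standardGeneric("classMap"))

#' @rdname accessors
#' @export
setGeneric("tauHat", function(object) standardGeneric("tauHat"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("fitError", function(object) standardGeneric("fitError"))

setMethod("rateMap", "SampleModel", function(object)
  object@rate * object@excitationScale)
setMethod("tauMap", "SampleModel", function(object) object@tau)
setMethod("photonCounts", "AcquisitionResult", function(object) object@counts)
setMethod("decayHist", "AcquisitionResult", function(object) object@hist)
setMethod("exposure", "ExposureMap", function(object) object@E)
setMethod("exposure", "AcquisitionResult", function(object) object@exposureUsed)
setMethod("roiMask", "ExposureMap", function(object) object@roi)
setMethod("classMap", "ExposureMap", function(object) object@classMap)
setMethod("tauHat", "LifetimeImage", function(object) object@tauHat)
setMethod("validMask", "LifetimeImage", function(object) object@valid)
setMethod("fitError", "LifetimeImage", function(object) object@fitError)

setMethod("show", "SampleModel", function(object) {
  d <- dim(object@rate)
  on <- object@rate > 0
  cat(sprintf("SampleModel %d x %d pixels\n", d[1], d[2]))
  cat(sprintf("  emitting pixels: %d (%.1f%%), rate %.3g-%.3g photons/us\n",
              sum(on), 100 * mean(on),
              if (any(on)) min(object@rate[on]) else 0,
              if (any(on)) max(object@rate[on]) else 0))
  if (any(on))
    cat(sprintf("  tau %.3g-%.3g ns%s\n", min(object@tau[on]),
                max(object@tau[on]),
                if (length(object@frac2)) " (bi-exponential)" else ""))
  cat(sprintf("  dcr %.3g counts/s, excitation scale %.3g\n",
              object@dcr, object@excitationScale))
})

setMethod("show", "AcqParams", function(object) {
  cat(sprintf(
    "AcqParams: %.3g MHz rep rate (%.4g ns period), %g ps bins x %d,\n",
    object@repRate / 1e6, 1e9 / object@repRate, object@binWidthPs,
    object@windowBins))
  cat(sprintf("  IRF sigma %g ps, decay origin %.3g ns\n",
              object@irfSigmaPs, object@t0Ns))
})

setMethod("show", "ExposureMap", function(object) {
  d <- dim(object@E)
  nz <- object@E[object@roi]
  cat(sprintf("ExposureMap %d x %d: %d ROI pixels (%.1f%%)\n",
              d[1], d[2], sum(object@roi), 100 * mean(object@roi)))
  if (length(nz))
    cat(sprintf("  dwell %g-%g us (caps %g/%g, step %g), target %g photons\n",
                min(nz), max(nz), object@tMin, object@tMax, object@step,
                object@iTarget))
})

setMethod("show", "AcquisitionResult", function(object) {
  d <- dim(object@counts)
  cat(sprintf("AcquisitionResult %d x %d: %.4g photons total", d[1], d[2],
              sum(object@counts)))
  cat(sprintf(", %s histograms\n",
              if (length(object@hist)) sprintf("%d-bin", dim(object@hist)[3])
              else "no"))
  cat(sprintf("  predicted frame time %.4g s (seed %d)\n",
              object@predictedTime, object@seed))
})

setMethod("show", "ScanWaveform", function(object) {
  cat(sprintf(
    "ScanWaveform: %d samples at %.3g MS/s (%.4g s), %d pixels visited\n",
    length(object@vx), object@f / 1e6, length(object@vx) / object@f,
    nrow(object@pixelSpans)))
})

setMethod("show", "LifetimeImage", function(object) {
  d <- dim(object@tauHat)
  v <- object@valid
  cat(sprintf("LifetimeImage %d x %d: %.1f%% valid\n", d[1], d[2],
              100 * mean(v)))
  if (any(v))
    cat(sprintf("  tau %.3g-%.3g ns (median %.3g)\n",
                min(object@tauHat[v]), max(object@tauHat[v]),
                stats::median(object@tauHat[v])))
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport\n")
  print(object@arms, digits = 4)
  cat("deltas (%):\n")
  print(round(object@deltas, 2))
})
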