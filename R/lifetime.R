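# Truncated-exponential mean: m(tau) = tau - T*exp(-T/tau)/(1-exp(-T/tau)),
# the expected arrival time of an exponential decay observed on a window of
# length T (equivalently of the wrapped/incomplete decay at the laser
# period). Monotone increasing in tau, with range (0, T/2).
truncExpMean <- function(tau, T) {
  x <- T / tau
  ifelse(x > 700, tau, tau - T * exp(-x) / (1 - exp(-x)))
}

# Invert truncExpMean for tau given a measured mean m on window T.
solveTruncatedTau <- function(m, T) {
  if (!is.finite(m) || m <= 0) return(0)
  if (m >= T / 2) return(NA_real_)   # beyond the model's range
  g <- function(tau) truncExpMean(tau, T) - m
  upper <- T
  while (g(upper) < 0) upper <- upper * 10
  stats::uniroot(g, c(1e-9, upper), tol = 1e-10)$root
}

# Anchor bin of a decay: peak of the histogram after light smoothing (5-bin
# boxcar) to keep the anchor stable at low photon counts; ties resolve to the
# earliest bin.
peakBin <- function(hist, smooth = 5L) {
  if (length(hist) < smooth || smooth <= 1) return(which.max(hist))
  s <- stats::filter(hist, rep(1 / smooth, smooth), sides = 2)
  s[is.na(s)] <- -Inf
  k <- which.max(s)
  # refine to the raw maximum inside the smoothed peak's neighbourhood
  lo <- max(1, k - (smooth %/% 2)); hi <- min(length(hist), k + (smooth %/% 2))
  lo + which.max(hist[lo:hi]) - 1L
}

#' Centre-of-mass (CMM) lifetime estimate of a decay histogram
#'
#' Locates the decay start at the histogram peak (after light smoothing so
#' the anchor is stable at low counts), opens the measurement window
#' \code{startOffset} bins later, subtracts a constant background per bin
#' (floored at 0), and takes the mean arrival time over the bins from the
#' window start to the window end, with times at bin centres relative to the
#' start edge:
#' \deqn{\hat\tau_{raw} = \sum_i (t_i - t_0) n_i / \sum_i n_i.}
#' Opening the window just past the peak exploits the memorylessness of the
#' exponential — times past any edge beyond the decay origin are again
#' exponential — which makes the estimate insensitive to where within the
#' peak bin the decay actually starts, at the price of a few early photons.
#'
#' The raw mean is biased low because the observation window truncates the
#' decay (equivalently, the periodic excitation wraps it); with
#' \code{correctTruncation} the estimate solves
#' \eqn{m = \tau - T e^{-T/\tau} / (1 - e^{-T/\tau})} for \eqn{\tau} by a
#' monotone 1-D root find, where \eqn{T} is the time from the window start
#' to the window end. CMM is the estimator of choice at low light (~250
#' photons per pixel); it assumes a mono-exponential decay and returns the
#' intensity-weighted average lifetime for mixtures.
#'
#' @param hist numeric vector of counts per bin.
#' @param params an [AcqParams-class] (supplies the bin width).
#' @param backgroundPerBin expected background counts per bin to subtract.
#' @param correctTruncation apply the truncation correction (default TRUE).
#' @param startOffset bins between the peak and the window start (default 2,
#'   enough to clear peak-bin alignment and IRF jitter at default settings).
#' @return estimated lifetime, ns; \code{NA} when no decay signal remains
#'   after background subtraction or the mean lies outside the model's range
#'   (the caller flags such pixels invalid). A histogram fully concentrated
#'   at or before the peak yields 0 (a zero-width decay).
#' @export
cmmLifetime <- function(hist, params = acqParams(), backgroundPerBin = 0,
                        correctTruncation = TRUE, startOffset = 2L) {
  stopIfNot(is.numeric(hist) && all(hist >= 0),
            "hist must be non-negative counts")
  if (sum(hist) == 0) return(NA_real_)
  bwNs <- params@binWidthPs / 1000
  B <- length(hist)
  k0 <- peakBin(hist)
  ks <- min(k0 + startOffset, B)
  seg <- pmax(hist[ks:B] - backgroundPerBin, 0)
  tot <- sum(seg)
  if (tot <= 0) {
    # photons exist but none beyond the window start: zero-width decay
    if (sum(pmax(hist - backgroundPerBin, 0)) > 0) return(0)
    return(NA_real_)
  }
  m <- sum((seq_along(seg) - 0.5) * bwNs * seg) / tot
  if (!correctTruncation) return(m)
  T <- (B - ks + 1) * bwNs
  solveTruncatedTau(m, T)
}

#' Least-squares mono-exponential decay fit
#'
#' Weighted least squares of \eqn{A e^{-t/\tau} + b} on the bins from the
#' histogram peak to the window end via Levenberg-Marquardt, with Poisson
#' weights refined in two passes: an initial fit weighted by the observed
#' counts (floored at 1) and a refit weighted by the fitted values —
#' weighting by the model variance avoids the low-count lifetime bias that
#' observed-count weights introduce. The gold standard at moderate photon
#' counts (> 1000); below that its variance grows quickly. The fit error is
#' the reduced chi-square of the refit; \code{normFitError} additionally
#' divides by the pixel's photon count, a per-pixel reliability metric
#' comparable across exposure levels.
#'
#' @param hist numeric vector of counts per bin.
#' @param params an [AcqParams-class].
#' @return list with \code{tau} (ns), \code{amplitude} (counts at the
#'   origin), \code{offset} (counts/bin), \code{fitError} (reduced
#'   chi-square), \code{normFitError}, and \code{converged}. On
#'   non-convergence \code{converged} is FALSE and \code{tau} is \code{NA}.
#' @export
lsFitLifetime <- function(hist, params = acqParams()) {
  stopIfNot(is.numeric(hist) && all(hist >= 0),
            "hist must be non-negative counts")
  bad <- list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
              fitError = NA_real_, normFitError = NA_real_, converged = FALSE)
  if (sum(hist) == 0) return(bad)
  bwNs <- params@binWidthPs / 1000
  k0 <- peakBin(hist)
  y <- hist[k0:length(hist)]
  if (sum(y[-1] > 0) < 3) return(bad)   # need >= 3 informative tail bins
  t <- (seq_along(y) - 1) * bwNs
  nTail <- max(3, round(length(y) * 0.1))
  b0 <- mean(y[(length(y) - nTail + 1):length(y)])
  A0 <- max(y[1] - b0, 1e-3)
  pos <- which(y - b0 > 0 & t > 0)
  tau0 <- if (length(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos] - b0) ~ t[pos]))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else 2
  } else 2
  tau0 <- min(max(tau0, bwNs), max(t))
  fit <- tryCatch({
    f1 <- minpack.lm::nlsLM(y ~ A * exp(-t / tau) + b,
                            start = list(A = A0, tau = tau0, b = max(b0, 0)),
                            weights = 1 / pmax(y, 1),
                            lower = c(0, bwNs / 100, 0),
                            control = minpack.lm::nls.lm.control(maxiter = 100))
    wts <- 1 / pmax(stats::fitted(f1), 1)
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + b,
                      start = as.list(stats::coef(f1)), weights = wts,
                      lower = c(0, bwNs / 100, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 100))
  }, error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  chi2 <- sum((y - yhat)^2 / pmax(yhat, 1)) / max(length(y) - 3, 1)
  list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
       offset = unname(cf["b"]), fitError = chi2,
       normFitError = chi2 / sum(hist), converged = TRUE)
}

#' Lifetime validity rule: peak at least five times the noise
#'
#' A pixel's decay supports a lifetime estimate when the peak bin count is at
#' least five times the expected per-bin background (dark counts plus optical
#' scattering) — at typical settings roughly 100 photons — and the total
#' count reaches the configurable floor.
#'
#' @param hist numeric vector of counts per bin.
#' @param noisePerBin expected background counts per bin, >= 0.
#' @param minTotal optional total-count floor (default 0: peak rule only).
#' @return logical.
#' @export
validityMask <- function(hist, noisePerBin, minTotal = 0) {
  stopIfNot(noisePerBin >= 0, "noisePerBin must be >= 0")
  tot <- sum(hist)
  tot > 0 && max(hist) >= 5 * noisePerBin && tot >= minTotal
}

#' Assemble a lifetime image from an acquisition
#'
#' Applies the validity rule per pixel and estimates lifetimes for valid
#' pixels only, by CMM (default) or least-squares fitting; the fit-error map
#' is filled where the LS estimator runs, with the photon-normalized reduced
#' chi-square (reliability improves with the photon budget).
#'
#' @param acq an [AcquisitionResult-class] with recorded histograms.
#' @param params an [AcqParams-class] matching the acquisition's binning.
#' @param estimator \code{"cmm"} or \code{"ls"}.
#' @param noisePerBin expected background counts per bin: a scalar or a
#'   matrix (e.g. scale by each pixel's dwell).
#' @param minTotal total-count validity floor.
#' @param backgroundPerBin expected background actually present per bin,
#'   subtracted inside the CMM estimator (default 0). Note this is distinct
#'   from \code{noisePerBin}, which only gates validity: subtracting the
#'   validity level from sparse decays would clip their tails.
#' @return a [LifetimeImage-class].
#' @export
lifetimeImage <- function(acq, params = acqParams(),
                          estimator = c("cmm", "ls"), noisePerBin = 0,
                          minTotal = 0, backgroundPerBin = 0) {
  estimator <- match.arg(estimator)
  stopIfNot(is(acq, "AcquisitionResult"), "acq must be an AcquisitionResult")
  stopIfNot(length(acq@hist) > 0,
            "acquisition has no recorded histograms")
  stopIfNot(abs(acq@binWidthPs - params@binWidthPs) < 1e-9,
            "params bin width must match the acquisition")
  d <- dim(acq@hist)
  h <- d[1]; w <- d[2]
  nb <- if (length(noisePerBin) == 1) matrix(noisePerBin, h, w) else noisePerBin
  bg <- if (length(backgroundPerBin) == 1) matrix(backgroundPerBin, h, w)
        else backgroundPerBin
  tau <- matrix(NA_real_, h, w)
  fe <- matrix(NA_real_, h, w)
  valid <- matrix(FALSE, h, w)
  hm <- matrix(acq@hist, h * w, d[3])
  for (i in seq_len(h * w)) {
    hv <- hm[i, ]
    if (!validityMask(hv, nb[i], minTotal)) next
    if (estimator == "cmm") {
      est <- cmmLifetime(hv, params, backgroundPerBin = bg[i])
      if (is.na(est) || est <= 0) next   # degenerate zero-width decays too
      tau[i] <- est
      valid[i] <- TRUE
    } else {
      fit <- lsFitLifetime(hv, params)
      if (!fit$converged) next
      tau[i] <- fit$tau
      fe[i] <- fit$normFitError
      valid[i] <- TRUE
    }
  }
  new("LifetimeImage", tauHat = tau, valid = valid, fitError = fe,
      counts = acq@counts)
}

#' Fraction of pixels with a valid lifetime
#'
#' @param img a [LifetimeImage-class].
#' @return ratio in [0, 1].
#' @export
lifetimeAvailability <- function(img) {
  stopIfNot(is(img, "LifetimeImage"), "img must be a LifetimeImage")
  mean(img@valid)
}
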