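# Shared fixtures: small samples and parameter sets built in code.

quickParams <- function(...) acqParams(...)

# uniform mono-exponential sample: every pixel identical, for replicate
# statistics
uniformSample <- function(h, w, rate, tau, dcr = 0) {
  new("SampleModel", rate = matrix(rate, h, w), tau = matrix(tau, h, w),
      dcr = dcr, excitationScale = 1)
}

# the standard heterogeneous phantom used across planner/evaluation tests
standardPhantom <- function(shape = c(96, 96), seed = 11L)
  twoSpeciesPhantom(shape, seed = seed)

# noise-free binned mono-exponential decay: origin at the left edge of bin
# `origin`, truncated at the window end, scaled to `total` photons
noiselessDecay <- function(tau, params, origin = 6L, total = 1e6) {
  B <- params@windowBins
  bw <- params@binWidthPs / 1000
  edges <- (0:(B - origin + 1)) * bw
  p <- diff(1 - exp(-edges / tau))
  h <- c(rep(0, origin - 1), p)
  h / sum(h) * total
}

# brute-force Otsu oracle: naive double loop over candidate thresholds
otsuBruteForce <- function(histogram, levels = seq_along(histogram) - 1) {
  best <- -Inf; bestLev <- NA
  tot <- sum(histogram)
  for (i in seq_along(levels)[-length(levels)]) {
    w0 <- sum(histogram[1:i]) / tot
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(histogram[1:i] * levels[1:i]) / sum(histogram[1:i])
    sel <- (i + 1):length(levels)
    mu1 <- sum(histogram[sel] * levels[sel]) / sum(histogram[sel])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; bestLev <- levels[i] }
  }
  bestLev
}
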