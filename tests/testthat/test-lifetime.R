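test_that("CMM recovers noise-free exponentials; truncation correction", {
  pp <- quickParams()
  for (tau in c(0.8, 2.5, 4.0)) {
    h <- noiselessDecay(tau, pp)
    expect_equal(cmmLifetime(h, pp), tau, tolerance = 0.05 / tau)
    # within half a bin width in absolute terms
    expect_lt(abs(cmmLifetime(h, pp) - tau), 0.05)
  }
  # on a short window the raw mean is visibly biased low and the
  # truncation correction removes the bias
  ppShort <- acqParams(windowBins = 100L)      # 10 ns window
  h <- noiselessDecay(2.5, ppShort)
  raw <- cmmLifetime(h, ppShort, correctTruncation = FALSE)
  cor <- cmmLifetime(h, ppShort)
  expect_lt(raw, 2.5 - 0.2)    # truncation pulls the raw mean well down
  expect_equal(cor, 2.5, tolerance = 0.02)
})

test_that("degenerate decays are flagged rather than estimated", {
  pp <- quickParams()
  # zero-width decay: everything at the peak
  h <- numeric(500); h[10] <- 300
  expect_equal(cmmLifetime(h, pp), 0)
  expect_true(is.na(cmmLifetime(numeric(500), pp)))
  # all-background histogram: nothing left after subtraction
  hb <- rep(2, 500)
  expect_true(is.na(cmmLifetime(hb, pp, backgroundPerBin = 2)))
})

test_that("CMM is accurate at its ~250-photon operating point", {
  pp <- quickParams()
  sm <- uniformSample(10, 20, 2.5, 2.0)
  est <- numeric(0)
  for (r in 1:2) {     # 2 x 200 replicate pixels at ~250 photons
    acq <- simulateAcquisition(sm, matrix(100, 10, 20), pp,
                               seed = 100L + r)
    hm <- matrix(decayHist(acq), 200, 500)
    est <- c(est, apply(hm, 1, cmmLifetime, params = pp))
  }
  expect_gte(length(est), 200)
  expect_equal(mean(est), 2.0, tolerance = 0.05)
})

test_that("CMM precision scales as one over root photons", {
  pp <- quickParams()
  tauOf <- function(rate, seed) {
    sm <- uniformSample(15, 15, rate, 2.0)
    acq <- simulateAcquisition(sm, matrix(100, 15, 15), pp, seed = seed)
    hm <- matrix(decayHist(acq), 225, 500)
    apply(hm, 1, cmmLifetime, params = pp)
  }
  sdN <- stats::sd(c(tauOf(2.5, 41L), tauOf(2.5, 42L)))    # ~250 photons
  sd4N <- stats::sd(c(tauOf(10, 43L), tauOf(10, 44L)))     # ~1000 photons
  expect_equal(sdN / sd4N, 2, tolerance = 0.2)
})

test_that("least-squares fit recovers exponentials and degrades low light", {
  pp <- quickParams()
  # noise-free model samples: zero-residual fit recovers tau exactly
  t <- (0:494) * 0.1
  y <- c(numeric(5), 800 * exp(-t / 2.2) + 3)
  fit <- lsFitLifetime(y, pp)
  expect_true(fit$converged)
  expect_equal(fit$tau, 2.2, tolerance = 1e-4)
  expect_equal(fit$offset, 3, tolerance = 1e-3)
  expect_lt(fit$fitError, 1e-6)
  # 1e4-photon decay: within 2%
  sm <- uniformSample(4, 4, 100, 2.5)
  acq <- simulateAcquisition(sm, matrix(100, 4, 4), pp, seed = 51L)
  taus <- apply(matrix(decayHist(acq), 16, 500), 1, function(h)
    lsFitLifetime(h, pp)$tau)
  expect_equal(mean(taus), 2.5, tolerance = 0.02)
  # variance blows up at 100 photons relative to 1000 photons
  fitMany <- function(rate, seed) {
    smx <- uniformSample(10, 25, rate, 2.5)
    a <- simulateAcquisition(smx, matrix(100, 10, 25), pp, seed = seed)
    apply(matrix(decayHist(a), 250, 500), 1, function(h) {
      f <- lsFitLifetime(h, pp); if (f$converged) f$tau else NA
    })
  }
  v100 <- stats::var(fitMany(1, 61L), na.rm = TRUE)
  v1000 <- stats::var(fitMany(10, 62L), na.rm = TRUE)
  expect_gt(v100 / v1000, 5)
})

test_that("validity rule: peak at least five times the noise", {
  h <- numeric(500)
  expect_false(validityMask(h, 1))            # empty histogram
  h[7] <- 5
  expect_true(validityMask(h, 1))             # exactly 5x: inclusive
  expect_false(validityMask(h, 5 / 4.9))      # peak = 4.9x noise
  expect_false(validityMask(h, 0, minTotal = 10))
  expect_error(validityMask(h, -1), "noisePerBin")
})

test_that("lifetime images honor validity and recover region lifetimes", {
  pp <- quickParams()
  sm <- twoSpeciesPhantom(c(32, 32), seed = 8L)
  # all-zero exposure -> all-invalid image
  acq0 <- simulateAcquisition(sm, matrix(0, 32, 32), pp, seed = 1L)
  img0 <- lifetimeImage(acq0, pp)
  expect_equal(lifetimeAvailability(img0), 0)
  expect_true(all(is.na(tauHat(img0))))
  # high-count acquisition: region means within 5%
  acq <- simulateAcquisition(sm, matrix(400, 32, 32), pp, seed = 2L)
  img <- lifetimeImage(acq, pp, estimator = "cmm", noisePerBin = 0.5)
  rate <- rateMap(sm); tau <- tauMap(sm)
  expect_equal(mean(tauHat(img)[tau == 2.5 & validMask(img)]), 2.5,
               tolerance = 0.05)
  expect_equal(mean(tauHat(img)[tau == 0.8 & validMask(img)]), 0.8,
               tolerance = 0.05)
  # background pixels carry no valid lifetime
  expect_false(any(validMask(img)[rate == 0]))
  # availability ratio arithmetic
  expect_equal(lifetimeAvailability(img), mean(validMask(img)))
})

test_that("bi-exponential pixels yield an intensity-weighted average", {
  pp <- quickParams()
  sm <- new("SampleModel", rate = matrix(40, 8, 8),
            tau = matrix(0.8, 8, 8), tau2 = matrix(3.0, 8, 8),
            frac2 = matrix(0.5, 8, 8), dcr = 0, excitationScale = 1)
  acq <- simulateAcquisition(sm, matrix(100, 8, 8), pp, seed = 77L)
  taus <- apply(matrix(decayHist(acq), 64, 500), 1, cmmLifetime,
                params = pp)
  # between the two components, near the photon-weighted mean 1.9
  expect_gt(mean(taus), 0.8)
  expect_lt(mean(taus), 3.0)
  expect_equal(mean(taus), 1.9, tolerance = 0.1)
})

test_that("more dwell on dim pixels never reduces expected availability", {
  pp <- quickParams()
  sm <- uniformSample(20, 20, 1.17, 2.5)
  avail <- function(E, seed) {
    a <- simulateAcquisition(sm, matrix(E, 20, 20), pp, seed = seed)
    lifetimeAvailability(lifetimeImage(a, pp, noisePerBin = 0.8))
  }
  a100 <- mean(vapply(1:3, function(s) avail(100, s), numeric(1)))
  a250 <- mean(vapply(1:3, function(s) avail(250, 10L + s), numeric(1)))
  expect_gte(a250, a100)
})
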