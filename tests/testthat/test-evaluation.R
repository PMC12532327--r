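test_that("count-histogram statistics follow their definitions", {
  cc <- matrix(5, 4, 4)
  st <- countHistogramStats(cc)
  expect_equal(unname(st), c(5, 0, 0))          # constant: var 0, skew 0
  two <- matrix(c(10, 20), 4, 4)                 # symmetric two-point
  expect_equal(countHistogramStats(two)[["skewness"]], 0)
  withr::with_seed(3L, x <- matrix(stats::rpois(10000, 250), 100, 100))
  st2 <- countHistogramStats(x)
  expect_lt(abs(st2[["mean"]] - 250), 3 * sqrt(250 / 1e4))
  # Poisson skewness 1/sqrt(lambda), SE of skewness ~ sqrt(6/n)
  expect_lt(abs(st2[["skewness"]] - 1 / sqrt(250)), 3 * sqrt(6 / 1e4))
  expect_error(countHistogramStats(cc, matrix(FALSE, 4, 4)), "fewer than 2")
})

test_that("region fit errors average valid pixels and report NA when empty", {
  mkLife <- function(fe, valid) {
    tau <- matrix(NA_real_, 4, 4); tau[valid] <- 2
    new("LifetimeImage", tauHat = tau, valid = valid, fitError = fe,
        counts = matrix(100, 4, 4))
  }
  E <- matrix(c(rep(500, 8), rep(60, 8)), 4, 4)
  # all pixels invalid -> both undefined
  allBad <- mkLife(matrix(1, 4, 4), matrix(FALSE, 4, 4))
  expect_true(all(is.na(regionFitError(allBad, E))))
  # uniform fit-error field -> dim and bright both equal that value
  uni <- mkLife(matrix(0.42, 4, 4), matrix(TRUE, 4, 4))
  expect_equal(unname(regionFitError(uni, E)), c(0.42, 0.42))
})

test_that("a homogeneous sample at the target is the planner's fixed point", {
  # P ~ I_target everywhere, full-frame ROI: adaptive == uniform up to
  # photon noise, so every delta is near zero
  sm <- uniformSample(40, 40, 2.5, 2.0, dcr = 100)
  rep <- runExperimentSuite(sm, list(mode = "enhance", roiMode = "all",
                                     estimator = "cmm", seed = 3L))
  expect_lt(abs(rep@deltas[["enhancementPct"]]), 3)
  expect_lt(abs(rep@deltas[["speedupPct"]]), 1)
  expect_lt(abs(rep@deltas[["availabilityGainPct"]]), 1)
})

test_that("fast mode buys frame time on sparse scenes at unchanged SNR", {
  sm <- standardPhantom(c(64, 64), seed = 21L)   # ~55% empty background
  rep <- runExperimentSuite(sm, list(mode = "fast", estimator = "cmm",
                                     block = 16L, seed = 9L))
  expect_gt(rep@deltas[["speedupPct"]], 0)
  expect_lt(abs(rep@deltas[["availabilityGainPct"]]), 2)
  expect_lt(abs(rep@deltas[["enhancementPct"]]), 2)
})

test_that("enhance mode matches frame times and feeds dim regions", {
  sm <- standardPhantom(c(64, 64), seed = 21L)
  rep <- runExperimentSuite(sm, list(mode = "enhance", estimator = "ls",
                                     block = 16L, seed = 9L))
  arms <- rep@arms
  tUni <- arms$frameTime[arms$arm == "uniform"]
  tAd <- arms$frameTime[arms$arm == "adaptive(merged)"]
  # equal-time arms match within 1%
  expect_lt(abs(tUni - tAd) / tUni, 0.01)
  # merged ROI counts enhanced over the uniform reference
  expect_gt(rep@deltas[["enhancementPct"]], 0)
  # the intensity-inverted scan's histogram is narrower and less skewed
  iScan <- arms$arm == "adaptive(scan)"; iUni <- arms$arm == "uniform"
  expect_lt(arms$varCounts[iScan], arms$varCounts[iUni])
  expect_lt(abs(arms$skewness[iScan]), abs(arms$skewness[iUni]))
  # dim regions fit better under adaptive exposure; bright comparable
  expect_lt(arms$dimError[arms$arm == "adaptive(merged)"],
            arms$dimError[iUni])
})

test_that("dim pixels receive strictly more photons at matched frame time", {
  pp <- acqParams()
  sm <- standardPhantom(c(64, 64), seed = 31L)
  pre <- simulateAcquisition(sm, matrix(100, 64, 64), pp, seed = 41L)
  em <- planExposure(pre, dcr = 100, tPrescan = 100, block = 16L)
  ad <- simulateAcquisition(sm, em, pp, seed = 42L)
  merged <- mergeAcquisitions(pre, ad)
  # photon conservation across the merge is exact
  expect_identical(sum(photonCounts(merged)),
                   sum(photonCounts(pre)) + sum(photonCounts(ad)))
  # time-matched uniform reference
  tTotal <- predictedFrameTime(synthesizeWaveform(em)) +
    predictedFrameTime(rasterWaveform(c(64, 64), 100))
  dwellUni <- 100 * tTotal /
    predictedFrameTime(rasterWaveform(c(64, 64), 100))
  uni <- simulateAcquisition(sm, matrix(dwellUni, 64, 64), pp, seed = 43L,
                             recordHist = FALSE)
  dimSel <- classMap(em) == 1L
  expect_gt(mean(photonCounts(merged)[dimSel]),
            mean(photonCounts(uni)[dimSel]))
})

test_that("reports are reproducible from config plus seed", {
  sm <- standardPhantom(c(48, 48), seed = 5L)
  cfg <- list(mode = "fast", estimator = "cmm", block = 16L, seed = 13L)
  a <- runExperimentSuite(sm, cfg)
  b <- runExperimentSuite(sm, cfg)
  expect_identical(a@arms, b@arms)
  expect_identical(a@deltas, b@deltas)
})
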