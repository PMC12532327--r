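test_that("Otsu threshold equals exhaustive between-class-variance search", {
  # two well-separated values: the threshold separates them (all 10s fall
  # at or below it, all 200s above); ties resolve to the lowest level
  h <- numeric(256); h[11] <- 500; h[201] <- 500
  thr <- otsuThreshold(h, 0:255)
  expect_gte(thr, 10); expect_lt(thr, 200)
  # property: match the brute-force oracle on random 8-bit toy histograms
  withr::with_seed(31L, {
    for (i in 1:25) {
      hh <- stats::rpois(256, lambda = stats::runif(1, 0.2, 3))
      if (sum(hh > 0) < 2) next
      expect_identical(otsuThreshold(hh, 0:255), otsuBruteForce(hh, 0:255))
    }
  })
  expect_error(otsuThreshold(c(0, 10, 0, 0)), "nonzero")
})

test_that("Otsu separates a bimodal Gaussian mixture", {
  withr::with_seed(7L, {
    x <- round(c(stats::rnorm(5000, 20, 5), stats::rnorm(5000, 180, 5)))
    x <- pmin(pmax(x, 0), 255)
  })
  thr <- otsuThreshold(tabulate(x + 1, 256), 0:255)
  expect_gt(thr, 20); expect_lt(thr, 180)
})

test_that("adaptive Otsu reduces to the global threshold when homogeneous", {
  withr::with_seed(13L, {
    img <- matrix(sample(c(5L, 200L), 64 * 64, TRUE), 64, 64)
  })
  lv <- 0:max(img)
  glob <- otsuThreshold(tabulate(as.vector(img) + 1L, length(lv)), lv)
  thr <- adaptiveOtsu(img, block = 16)
  expect_true(all(abs(thr - glob) < 1e-9))
  # block = full image is identical to the global case
  thr2 <- adaptiveOtsu(img, block = 64)
  expect_true(all(thr2 == glob))
})

test_that("per-block thresholds match blockwise brute-force Otsu", {
  # four 16x16 blocks with shifted two-level intensities
  img <- matrix(0L, 32, 32)
  withr::with_seed(17L, {
    shifts <- c(0L, 60L, 120L, 180L)
    k <- 1
    for (bi in 0:1) for (bj in 0:1) {
      blk <- matrix(sample(c(10L, 100L) + shifts[k], 256, TRUE), 16, 16)
      img[bi * 16 + 1:16, bj * 16 + 1:16] <- blk
      k <- k + 1
    }
  })
  thr <- adaptiveOtsu(img, block = 16, interpolate = FALSE)
  lv <- 0:max(img)
  for (bi in 0:1) for (bj in 0:1) {
    ri <- bi * 16 + 1:16; ci <- bj * 16 + 1:16
    oracle <- otsuBruteForce(tabulate(as.vector(img[ri, ci]) + 1L,
                                      length(lv)), lv)
    expect_true(all(thr[ri, ci] == oracle))
  }
  expect_warning(adaptiveOtsu(matrix(5L, 16, 16), block = 8), "degenerate")
})

test_that("Otsu agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  withr::with_seed(19L, {
    img <- matrix(sample(0:255, 64 * 64, TRUE,
                         prob = c(rep(4, 64), rep(1, 128), rep(4, 64))),
                  64, 64)
  })
  ours <- otsuThreshold(tabulate(as.vector(img) + 1L, 256), 0:255)
  ref <- EBImage::otsu(img / 255, range = c(0, 1), levels = 256) * 255
  expect_lt(abs(ours - ref), 1.5)   # conventions differ by at most one level
})

test_that("pixel classification follows the dark-count/threshold rule", {
  # counts below the dark expectation everywhere -> empty ROI
  counts <- matrix(0, 8, 8)
  cl <- classifyPixels(counts, dcr = 1e6, tPrescanUs = 100,
                       othresh = 0, iTarget = 250)
  expect_false(any(cl$roi))
  # strict inequality: counts equal to alpha stay outside the ROI
  counts2 <- matrix(10, 4, 4)
  cl2 <- classifyPixels(counts2, dcr = 0, tPrescanUs = 100, othresh = 10,
                        iTarget = 250)
  expect_false(any(cl2$roi))
  # the three-way rule
  counts3 <- matrix(c(0, 120, 600, 0), 2, 2)
  cl3 <- classifyPixels(counts3, dcr = 0, tPrescanUs = 100, othresh = 10,
                        iTarget = 250)
  expect_identical(as.vector(cl3$classMap), c(0L, 1L, 2L, 0L))
  expect_error(classifyPixels(counts3, dcr = -1, 100, 10, 250), "negative")
})

test_that("intensity inversion maps counts to capped quantized dwells", {
  roi <- matrix(TRUE, 1, 3)
  P <- matrix(c(117, 1000, 250), 1, 3)
  em <- computeExposureMap(P, roi, iTarget = 250, tBaseline = 100,
                           tMin = 50, tMax = 600, step = 1)
  # 100*250/117 = 213.675 -> 214; 25 -> clamped to 50; fixed point -> 100
  expect_equal(as.vector(exposure(em)), c(214, 50, 100))
  expect_identical(as.vector(uncappedMask(em)), c(TRUE, FALSE, TRUE))
  # dim pixel below target is class 1, bright class 2
  expect_identical(as.vector(classMap(em)), c(1L, 2L, 2L))
})

test_that("planned dwell is non-increasing in the pre-scan count", {
  P <- matrix(seq(42, 499, length.out = 100), 1, 100)
  em <- computeExposureMap(P, matrix(TRUE, 1, 100), 250, 100,
                           tMin = 50, tMax = 600, step = 1)
  expect_true(all(diff(as.vector(exposure(em))) <= 0))
})

test_that("exposure amplification is bounded by tMax/Tbaseline", {
  # a sufficiently dim phantom drives dwells to the cap; with caps 50-800
  # and a 100 us baseline the max amplification is exactly 8
  sm <- twoSpeciesPhantom(c(48, 48), brightRate = 0.6, dimRate = 0.15,
                          seed = 9L)
  pre <- simulateAcquisition(sm, matrix(100, 48, 48), quickParams(),
                             seed = 10L, recordHist = FALSE)
  em <- planExposure(pre, dcr = 100, tPrescan = 100, iTarget = 250,
                     tMin = 50, tMax = 800, step = 1, block = 16)
  amp <- exposure(em) / 100
  expect_true(all(amp <= 8))
  expect_equal(max(amp), 8)
})

test_that("planning rejects inconsistent parameters", {
  P <- matrix(100, 2, 2); roi <- matrix(TRUE, 2, 2)
  expect_error(computeExposureMap(P, roi, iTarget = 0, tBaseline = 100),
               "iTarget")
  expect_error(computeExposureMap(P, roi, 250, 100, tMin = 60, tMax = 50),
               "tMin")
  expect_error(computeExposureMap(P, roi, 250, 100, step = 0), "step")
  P0 <- matrix(0, 2, 2)
  expect_error(computeExposureMap(P0, roi, 250, 100), "internal")
})
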