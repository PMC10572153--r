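test_that("the insert center is recovered to subpixel accuracy", {
  center <- c(45.3, 49.1)
  spec <- phantomSpec(150, backgroundHU = 35, edgeBlurSigma = 0.4, nSlices = 2,
                      matrixSize = 256L, pixelSpacing = 0.371, seed = 5,
                      insert = list(center = center, diameter = 20, contrast = 800))
  stk <- generatePhantomStack(spec, noiseModel(100, 0.15, targetSd = 20))
  est <- estimateCenter(stk, center + c(1.5, -1.2), searchRadius = 18)
  expect_lt(max(abs(est - center)), 0.1 * 0.371)
})

test_that("a pixel-centered symmetric insert returns exactly that center", {
  spec <- insertPhantomSpec(sigma = 0.4, contrast = 500, size = 256L)
  stk <- generatePhantomStack(spec, NULL)
  truth <- c(1, 1) * 256 / 2 * 0.742
  est <- estimateCenter(stk, truth + c(0.9, -0.7), searchRadius = 22)
  expect_equal(est, truth, tolerance = 1e-9)
})

test_that("a stack of pure noise raises insert-not-found", {
  m <- noiseModel(1, 0.1, rise = 0, targetSd = 20)
  stk <- noiseOnlyStack(3, 128, 0.742, m)
  expect_error(estimateCenter(stk, c(47, 47), searchRadius = 20), "insert not found")
})

test_that("the 40 keV iodine contrast is recovered from the edge profile", {
  spec <- insertPhantomSpec(sigma = 0.5, contrast = 1260, nSlices = 20, seed = 2)
  stk <- generatePhantomStack(spec, noiseModel(100, 0.15, targetSd = 40))
  prof <- radialEsf(stk, c(1, 1) * 256 / 2 * 0.742, range = c(6.25, 22.5),
                    fillEmpty = TRUE)
  expect_equal(edgeContrast(prof), 1260, tolerance = 10 / 1260)
})

test_that("empty radial bins inside the fit range are rejected with a bin index", {
  stk <- generatePhantomStack(insertPhantomSpec(sigma = 0.5, contrast = 500), NULL)
  expect_error(
    radialEsf(stk, c(1, 1) * 256 / 2 * 0.742, range = c(2, 22.5),
              binWidth = 0.02),
    "empty radial bin")
})

test_that("doubling the pooled slices roughly halves the ESF bin noise variance", {
  truthStk <- generatePhantomStack(insertPhantomSpec(sigma = 0.5, contrast = 500), NULL)
  ctr <- c(1, 1) * 256 / 2 * 0.742
  truth <- radialEsf(truthStk, ctr, range = c(8, 18), binWidth = 0.2,
                     fillEmpty = TRUE)@esf
  binVar <- function(nSlices, seed) {
    spec <- insertPhantomSpec(sigma = 0.5, contrast = 500, nSlices = nSlices,
                              seed = seed)
    stk <- generatePhantomStack(spec, noiseModel(1, 0.1, rise = 0, targetSd = 40))
    esf <- radialEsf(stk, ctr, range = c(8, 18), binWidth = 0.2,
                     fillEmpty = TRUE)@esf
    mean((esf - truth)^2)
  }
  v8 <- mean(vapply(1:6, function(s) binVar(8L, 900 + s), numeric(1)))
  v16 <- mean(vapply(1:6, function(s) binVar(16L, 950 + s), numeric(1)))
  expect_gt(v8 / v16, 1.5)
  expect_lt(v8 / v16, 2.8)
})

test_that("Gaussian blur is recovered: TTF matches its analytic transfer to f50", {
  stk <- generatePhantomStack(insertPhantomSpec(sigma = 0.5, contrast = 500), NULL)
  ttf <- estimateTtf(stk)
  expect_equal(ttf@ttf[1L], 1, tolerance = 1e-6)
  f50 <- ttfF50(ttf)
  expect_equal(f50, gaussF50(0.5), tolerance = 0.02)
  idx <- ttf@freq > 0 & ttf@freq <= f50
  analytic <- exp(-2 * pi^2 * 0.5^2 * ttf@freq[idx]^2)
  expect_lt(max(abs(ttf@ttf[idx] - analytic) / analytic), 0.02)
})

test_that("blur recovery holds across the sigma grid (noiseless)", {
  for (sig in c(0.3, 0.8, 1.2)) {
    stk <- generatePhantomStack(insertPhantomSpec(sigma = sig, contrast = 500), NULL)
    expect_equal(ttfF50(estimateTtf(stk)), gaussF50(sig), tolerance = 0.02,
                 label = sprintf("f50 at sigma %.1f", sig))
  }
})

test_that("f50 stays within 5% at the 160-slice budget under realistic noise", {
  for (cfg in list(list(contrast = 1260, sd = 80, seed = 21),
                   list(contrast = 390, sd = 35, seed = 22))) {
    spec <- insertPhantomSpec(sigma = 0.5, contrast = cfg$contrast,
                              nSlices = 160, seed = cfg$seed)
    stk <- generatePhantomStack(spec, noiseModel(100, 0.15, targetSd = cfg$sd))
    expect_equal(ttfF50(estimateTtf(stk)), gaussF50(0.5), tolerance = 0.05,
                 label = sprintf("f50 at contrast %d", cfg$contrast))
  }
})

test_that("an ideal step edge transfers as unity over the low-frequency band", {
  stk <- generatePhantomStack(insertPhantomSpec(sigma = 0, contrast = 500), NULL)
  ctr <- c(1, 1) * 256 / 2 * 0.742
  prof <- radialEsf(stk, ctr, range = c(6.25, 22.5), binWidth = 0.0742,
                    fillEmpty = TRUE)
  ttf <- ttfFromEsf(prof)
  low <- ttf@freq <= 0.3
  expect_gt(min(ttf@ttf[low]), 0.97)
})

test_that("rescaling all HU leaves the TTF unchanged; zero contrast is rejected", {
  stk <- generatePhantomStack(insertPhantomSpec(sigma = 0.5, contrast = 500), NULL)
  ctr <- c(1, 1) * 256 / 2 * 0.742
  p1 <- radialEsf(stk, ctr, range = c(6.25, 22.5), fillEmpty = TRUE)
  stk2 <- ctStack(voxels(stk) * 2.5, pixelSpacing(stk),
                  metadata = stackMetadata(stk))
  p2 <- radialEsf(stk2, ctr, range = c(6.25, 22.5), fillEmpty = TRUE)
  t1 <- ttfFromEsf(p1); t2 <- ttfFromEsf(p2)
  expect_equal(t2@ttf, t1@ttf, tolerance = 1e-10)
  flat <- new("EdgeProfile", binCenters = seq(0.05, 9.95, by = 0.1),
              esf = rep(10, 100), counts = rep(5L, 100), contrast = 0,
              center = c(0, 0), binWidth = 0.1, plateaus = list())
  expect_error(ttfFromEsf(flat), "contrast is zero")
})

test_that("f50 interpolation inverts an analytic Gaussian TTF; flat TTF errors", {
  f <- seq(0, 1.2, by = 0.01)
  for (sig in c(0.4, 0.5, 0.9)) {
    tt <- new("TTFResult", freq = f, ttf = exp(-2 * pi^2 * sig^2 * f^2),
              f50 = ctiq:::ttfCrossing(f, exp(-2 * pi^2 * sig^2 * f^2), 0.5),
              lsf = data.frame(), contrast = 1)
    expect_equal(ttfF50(tt), gaussF50(sig), tolerance = 2e-4)
  }
  flat <- new("TTFResult", freq = f, ttf = rep(1, length(f)), f50 = NA_real_,
              lsf = data.frame(), contrast = 1)
  expect_error(ttfF50(flat), "never falls below")
})

test_that("TTF distortion grows as the contrast-to-noise ratio falls", {
  # at very low CNR the measured curve may never cross 0.5, so quantify the
  # bias as the distortion of the transfer value at the analytic f50
  f50True <- gaussF50(0.5)
  distortion <- function(sdNoise, seeds) {
    mean(vapply(seeds, function(s) {
      spec <- insertPhantomSpec(sigma = 0.5, contrast = 120, nSlices = 24,
                                seed = s)
      stk <- generatePhantomStack(spec, noiseModel(100, 0.15, targetSd = sdNoise))
      ttf <- estimateTtf(stk)
      abs(stats::approx(ttf@freq, ttf@ttf, f50True)$y - 0.5)
    }, numeric(1)))
  }
  expect_gt(distortion(60, 201:206), distortion(8, 101:106))
})

test_that("pooling the ESF before differentiation beats averaging per-slice TTFs", {
  # compared via the transfer value at the analytic f50, which exists even
  # for noisy single-slice curves that never cross 0.5
  f50True <- gaussF50(0.5)
  ttfAt <- function(stk, slices) {
    ttf <- estimateTtf(stk, slices = slices)
    stats::approx(ttf@freq, ttf@ttf, f50True)$y
  }
  pooled <- perSlice <- numeric(0)
  for (seed in 301:312) {
    spec <- insertPhantomSpec(sigma = 0.5, contrast = 150, nSlices = 16,
                              seed = seed)
    stk <- generatePhantomStack(spec, noiseModel(100, 0.15, targetSd = 40))
    pooled <- c(pooled, ttfAt(stk, 1:16))
    perSlice <- c(perSlice, mean(vapply(1:16, function(k) ttfAt(stk, k),
                                        numeric(1))))
  }
  expect_lt(mean((pooled - 0.5)^2), mean((perSlice - 0.5)^2))
})
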