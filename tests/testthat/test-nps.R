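test_that("ROI extraction returns slice-major blocks of the requested size", {
  m <- noiseModel(1, 0.1, rise = 0, targetSd = 10)
  stk <- noiseOnlyStack(5, 64, 0.742, m)
  lay <- roiLayout(16L, rbind(c(16, 16), c(48, 48)), slices = 1:5)
  blocks <- extractRois(stk, lay)
  expect_length(blocks, 10L)
  expect_true(all(vapply(blocks, function(b) all(dim(b) == 16L), TRUE)))
  # identity crop: one ROI, one slice
  lay1 <- roiLayout(16L, c(16, 16), slices = 2L)
  b <- extractRois(stk, lay1)[[1L]]
  expect_identical(b, voxels(stk)[9:24, 9:24, 2])
  # block 3 is slice 2, ROI 1 (slice-major order)
  expect_identical(blocks[[3L]], voxels(stk)[9:24, 9:24, 2])
})

test_that("out-of-bounds and insert-overlapping ROIs are rejected by name", {
  m <- noiseModel(1, 0.1, rise = 0, targetSd = 10)
  stk <- noiseOnlyStack(2, 64, 0.742, m)
  expect_error(extractRois(stk, roiLayout(16L, c(2, 2), slices = 1L)),
               "ROI 1 .*outside")
  expect_error(extractRois(stk, roiLayout(16L, c(32, 32), slices = 1:3)),
               "slice 3")
  spec <- insertPhantomSpec(sigma = 0.3, contrast = 500, nSlices = 1, size = 128L)
  ins <- generatePhantomStack(spec, NULL)
  expect_error(extractRois(ins, roiLayout(24L, c(64, 64), slices = 1L)),
               "ROI 1 overlaps")
  # a corner ROI away from the central insert is fine
  expect_length(extractRois(ins, roiLayout(24L, c(20, 20), slices = 1L)), 1L)
})

test_that("degree-2 surfaces are removed exactly and residuals are zero mean", {
  x <- outer(rep(1, 32), seq_len(32))
  y <- t(x)
  surf <- 3 + 0.5 * x - 0.2 * y + 0.01 * x * y + 0.003 * x^2 - 0.002 * y^2
  expect_lt(max(abs(detrendRoi(surf))), 1e-9)
  set.seed(1)
  blk <- surf + matrix(rnorm(32^2), 32)
  expect_lt(abs(mean(detrendRoi(blk))), 1e-9)
  expect_error(detrendRoi(matrix(0, 4, 4)), "at least 8 x 8")
})

test_that("detrending a white block keeps its variance up to the 6-parameter correction", {
  set.seed(2)
  n <- 32^2
  ratio <- vapply(1:200, function(i) {
    blk <- matrix(rnorm(n, sd = 4), 32)
    stats::var(as.vector(detrendRoi(blk))) / stats::var(as.vector(blk))
  }, numeric(1))
  expect_equal(mean(ratio), 1 - 6 / n, tolerance = 0.01)
})

test_that("white-noise periodogram is flat at sigma^2 dx dy and integrates to sigma^2", {
  sp <- 0.742
  set.seed(3)
  blocks <- lapply(1:200, function(i) matrix(rnorm(64^2, sd = 10), 64))
  nps <- computeNps2d(lapply(blocks, detrendRoi), sp)
  level <- 100 * sp^2
  use <- nps@freq > 2 * nps@df
  expect_lt(max(abs(nps@nps1d[use] - level) / level), 0.10)
  tot <- sum(nps@nps2d) * diff(nps@freqU[1:2]) * diff(nps@freqV[1:2])
  expect_equal(tot, 100, tolerance = 0.02)
  expect_equal(noiseMagnitude(nps), 10, tolerance = 0.05)
})

test_that("degenerate inputs: all-zero blocks give a zero NPS and undefined metrics", {
  z <- computeNps2d(replicate(3, matrix(0, 16, 16), simplify = FALSE), 0.5)
  expect_true(all(z@nps2d == 0))
  expect_true(is.na(averageFrequency(z)))
  expect_error(npsMetrics(z), "identically zero")
  expect_error(computeNps2d(list(matrix(0, 16, 16), matrix(0, 8, 8)), 0.5),
               "share one size")
})

test_that("angular-integrated curve reproduces the 2-D integral and nNPS has unit area", {
  m <- noiseModel(c(120, 100), c(0.03, 0.16), targetSd = 30)
  blocks <- lapply(1:20, function(i)
    generateNoiseField(c(128, 128), 0.742, m, seed = 40 + i))
  nps <- computeNps2d(blocks, 0.742)
  tot <- sum(nps@nps2d) * diff(nps@freqU[1:2]) * diff(nps@freqV[1:2])
  expect_equal(sum(nps@npsAngular) * nps@df, tot, tolerance = 1e-9)
  expect_equal(sum(nps@nnps1d) * nps@df, 1, tolerance = 1e-6)
  expect_true(all(nps@nps2d >= 0))
  expect_equal(max(nps@freq), nps@nyquist, tolerance = nps@df / nps@nyquist)
})

test_that("a single-frequency spectrum puts f_av and the only peak on that bin", {
  # cosine grating concentrates the periodogram in one radial bin
  k <- 10
  g <- outer(rep(1, 64), cos(2 * pi * k * (0:63) / 64))
  nps <- computeNps2d(list(g), 1)
  f0 <- k / 64
  expect_equal(averageFrequency(nps), f0, tolerance = 1e-9)
  pk <- npsPeaks(nps)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$fpeak, f0, tolerance = 1e-9)
})

test_that("NPS scales as c^2, noise magnitude as |c|, frequencies unchanged", {
  m <- noiseModel(100, 0.15, targetSd = 15)
  blocks <- lapply(1:15, function(i)
    generateNoiseField(c(96, 96), 0.742, m, seed = 70 + i))
  a <- computeNps2d(blocks, 0.742)
  b <- computeNps2d(lapply(blocks, function(x) 3 * x), 0.742)
  expect_equal(b@nps2d, 9 * a@nps2d, tolerance = 1e-12)
  expect_equal(noiseMagnitude(b), 3 * noiseMagnitude(a), tolerance = 1e-12)
  expect_equal(averageFrequency(b), averageFrequency(a), tolerance = 1e-12)
  expect_equal(npsPeaks(b)$fpeak, npsPeaks(a)$fpeak, tolerance = 1e-12)
})

test_that("halving the pixel spacing doubles Nyquist and preserves physical metrics", {
  mCoarse <- noiseModel(100, 0.15, targetSd = 20)
  coarse <- computeNps2d(lapply(1:40, function(i)
    generateNoiseField(c(128, 128), 0.742, mCoarse, seed = 200 + i)), 0.742)
  fine <- computeNps2d(lapply(1:40, function(i)
    generateNoiseField(c(256, 256), 0.371, mCoarse, seed = 300 + i)), 0.371)
  expect_equal(fine@nyquist, 2 * coarse@nyquist)
  expect_equal(npsPeaks(fine)$fpeak[1L], npsPeaks(coarse)$fpeak[1L],
               tolerance = 2 * coarse@df / 0.15)
  # the band-limited spectrum carries the same total power on both grids
  expect_equal(noiseMagnitude(fine), noiseMagnitude(coarse), tolerance = 0.05)
})

test_that("default ROI layout reproduces the per-diameter sizes and slice budget", {
  lay <- defaultRoiLayout(26)
  expect_equal(lay@roiSize, 80L)
  expect_equal(nrow(lay@centers), 4L)
  expect_length(lay@slices, 180L)
  expect_equal(defaultRoiLayout(31)@roiSize, 104L)
  expect_equal(defaultRoiLayout(36)@roiSize, 120L)
})
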