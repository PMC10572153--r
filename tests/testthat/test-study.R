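# A deliberately small synthetic study used by several tests: full 512^2
# acquisition geometry but few slices and acquisitions.
tinyStudyConfig <- function(datasets = "A", diameters = c(26, 31),
                            kev = c(40, 70), nAcq = 1L, seed = 7L,
                            noiseBase = 14, blurBase = 0.45) {
  syntheticStudyConfig(
    datasets = datasets, diameters = diameters, kev = kev,
    noiseBase = noiseBase, blurBase = blurBase,
    nAcq = nAcq, slicesPerAcqNps = 4L, slicesPerAcqTtf = 4L,
    seed = seed)
}

test_that("the study grid enumerates every dataset x diameter x keV combination", {
  cfg <- syntheticStudyConfig(datasets = c("A", "B", "C"))
  expect_equal(nrow(cfg@grid), 3 * 3 * 4)
  expect_equal(anyDuplicated(with(cfg@grid, paste(dataset, diameter_cm, kev))), 0L)
  # contrast table is the 40-70 keV iodine ladder
  expect_equal(unique(cfg@grid$contrast[cfg@grid$kev == 40]), 1260)
  expect_equal(unique(cfg@grid$contrast[cfg@grid$kev == 70]), 390)
  expect_error(syntheticStudyConfig(kev = c(40, 80)), "contrastByKev")
})

test_that("a small end-to-end study fills every metric and is seed-deterministic", {
  cfg <- tinyStudyConfig()
  d1 <- withr::with_tempdir({
    runStudy(cfg, outDir = "run1")
  })
  expect_equal(nrow(d1), 4L)
  expect_true(all(d1$status == "ok"))
  expect_true(all(is.finite(d1$noise_magnitude)))
  expect_true(all(is.finite(d1$f50)))
  expect_true(all(is.finite(d1$dprime)))
  # measured edge contrast tracks the per-keV task contrast
  expect_equal(d1$contrast, d1$task_contrast, tolerance = 0.03)
  d2 <- runStudy(cfg)
  expect_identical(d1[names(d2)], d2)
})

test_that("identical config and seed write bit-identical results.csv files", {
  cfg <- tinyStudyConfig(diameters = 26, kev = c(40, 70))
  out <- withr::local_tempdir()
  runStudy(cfg, outDir = file.path(out, "a"))
  runStudy(cfg, outDir = file.path(out, "b"))
  a <- readBin(file.path(out, "a", "results.csv"), raw(),
               file.size(file.path(out, "a", "results.csv")))
  b <- readBin(file.path(out, "b", "results.csv"), raw(),
               file.size(file.path(out, "b", "results.csv")))
  expect_identical(a, b)
  expect_true(length(list.files(file.path(out, "a", "nps_curves"))) == 2)
  expect_true(length(list.files(file.path(out, "a", "ttf_curves"))) == 2)
})

test_that("a noiseless combination fails only its observer stage and is flagged", {
  cfg <- tinyStudyConfig(diameters = 26, kev = 40, noiseBase = 0)
  res <- runStudy(cfg)
  expect_equal(nrow(res), 1L)
  expect_match(res$status, "dprime failed")
  expect_true(is.na(res$dprime))
  expect_true(is.finite(res$f50))   # the TTF itself is fine without noise
})

test_that("percent differences reproduce a hand-computed mean and sample SD", {
  tab <- data.frame(
    dataset = rep(c("A", "B"), each = 4),
    kev = rep(c(40, 50, 60, 70), 2),
    m = c(110, 112, 109, 111, 100, 100, 100, 100))
  s <- percentDiffSummary(tab, "m", axis = "dataset", ref = "B", cmp = "A",
                          over = "kev")
  expect_equal(s$mean_pct, 10.5)
  expect_equal(s$sd_pct, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(s$sd_pct, 1.29, tolerance = 1e-2)
  expect_equal(s$n, 4L)
  expect_equal(attr(s, "diffs"), c(10, 12, 9, 11))
})

test_that("percent-difference summaries match a brute-force oracle on random tables", {
  set.seed(99)
  for (rep in 1:5) {
    a <- runif(6, 50, 150)
    b <- runif(6, 50, 150)
    tab <- data.frame(g = rep(c("X", "Y"), each = 6), lev = rep(1:6, 2),
                      v = c(a, b))
    s <- percentDiffSummary(tab, "v", axis = "g", ref = "Y", cmp = "X",
                            over = "lev")
    o <- brutePctSummary(a, b)
    expect_equal(s$mean_pct, o$mean, tolerance = 1e-12)
    expect_equal(s$sd_pct, o$sd, tolerance = 1e-12)
  }
})

test_that("identical conditions give 0 +/- 0 and zero references are rejected", {
  tab <- data.frame(g = rep(c("X", "Y"), each = 3), lev = rep(1:3, 2),
                    v = c(5, 6, 7, 5, 6, 7))
  s <- percentDiffSummary(tab, "v", axis = "g", ref = "Y", cmp = "X", over = "lev")
  expect_equal(s$mean_pct, 0)
  expect_equal(s$sd_pct, 0)
  tab$v[4] <- 0
  expect_error(percentDiffSummary(tab, "v", axis = "g", ref = "Y", cmp = "X",
                                  over = "lev"), "zero at lev = 1")
})

test_that("missing pairings are skipped and reported, not imputed", {
  tab <- data.frame(g = c("X", "X", "Y"), lev = c(1, 2, 1), v = c(11, 12, 10))
  s <- percentDiffSummary(tab, "v", axis = "g", ref = "Y", cmp = "X", over = "lev")
  expect_equal(s$n, 1L)
  expect_equal(attr(s, "skipped"), "2")
  expect_true(is.na(s$sd_pct))
})

test_that("the from-level-x-to-level-y convention uses the same machinery", {
  tab <- data.frame(kev = rep(c(40, 70), each = 2),
                    diam = rep(c(26, 31), 2),
                    noise = c(100, 120, 50, 60))
  s <- percentDiffSummary(tab, "noise", axis = "kev", ref = 40, cmp = 70,
                          over = "diam")
  expect_equal(s$mean_pct, -50)
  expect_equal(s$sd_pct, 0)
})
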