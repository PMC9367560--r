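# Synthetic nodule-growth generator.

test_that("growth parameter sampling is deterministic and class-separated", {
  set.seed(11)
  a <- sampleGrowthParams("IA")
  set.seed(11)
  b <- sampleGrowthParams("IA")
  expect_identical(a, b)

  set.seed(2)
  dtIA <- replicate(300, sampleGrowthParams("IA")@dtDouble)
  dtNon <- replicate(300, sampleGrowthParams("non-IA")@dtDouble)
  # IA doubling times sit below the 400-day fast-growth convention
  expect_gt(mean(dtIA < 400), 0.9)
  # and are stochastically shorter than non-IA ones
  expect_lt(wilcox.test(dtIA, dtNon, alternative = "less")$p.value, 1e-6)
})

test_that("a static nodule keeps a constant volume over any horizon", {
  p <- new("GrowthParams", modelKind = "exponential", v0 = 50, dtDouble = Inf,
           solid0 = 0.1, solidEnd = 0.1, noiseSd = 0, backgroundHu = -850)
  expect_equal(growthVolume(p, c(0, 100, 2813)), rep(50, 3))
})

test_that("Gompertz growth matches the exponential rate early and saturates", {
  vmax <- sphereVol(13)
  pe <- new("GrowthParams", modelKind = "exponential", v0 = 100,
            dtDouble = 300, solid0 = 0, solidEnd = 0, noiseSd = 0,
            backgroundHu = -850)
  pg <- new("GrowthParams", modelKind = "gompertz", v0 = 100,
            dtDouble = 300, solid0 = 0, solidEnd = 0, noiseSd = 0,
            backgroundHu = -850)
  # same initial relative growth rate: equal to first order in t
  expect_equal(growthVolume(pg, 5, vmax), growthVolume(pe, 5, vmax),
               tolerance = 1e-3)
  # saturating: always at or below the exponential, bounded by vmax
  t <- seq(0, 4000, by = 250)
  vg <- growthVolume(pg, t, vmax)
  expect_true(all(vg <= growthVolume(pe, t, vmax) + 1e-9))
  expect_true(all(vg <= vmax))
  expect_true(all(diff(vg) >= 0))
})

test_that("exponential growth doubles exactly at the doubling time", {
  p <- new("GrowthParams", modelKind = "exponential", v0 = 80, dtDouble = 365,
           solid0 = 0, solidEnd = 0, noiseSd = 0, backgroundHu = -850)
  expect_equal(growthVolume(p, 365), 160)
  expect_equal(growthVolume(p, 730), 320)
})

test_that("rendered sphere mass matches the analytic volume within one voxel shell", {
  v <- sphereVol(5)   # 523.598...
  rn <- renderNodule(v, 0.5, gridShape = c(32L, 32L, 32L), noiseSd = 0)
  shell <- 4 * pi * 5^2 * 1   # one 1-mm shell
  expect_lt(abs(maskVolumeMm3(rn$mask) - v), shell)
  # holds across radii (one-voxel-shell relative accuracy for r >= 3)
  for (r in 3:10) {
    rn <- renderNodule(sphereVol(r), 0, gridShape = c(32L, 32L, 32L))
    expect_lt(abs(maskVolumeMm3(rn$mask) - sphereVol(r)), 4 * pi * r^2)
  }
})

test_that("solid fraction controls the attenuation inside the mask", {
  v <- sphereVol(5)
  rn0 <- renderNodule(v, 0, noiseSd = 0)
  inMask <- rn0$mask@voxels > 0
  expect_true(all(rn0$image@voxels[inMask] < -300))   # pure ground glass
  rn1 <- renderNodule(v, 1, noiseSd = 0)
  expect_true(all(rn1$image@voxels[inMask] == 0))     # fully solid core
  # all HU stay within the clip band even with noise
  set.seed(1)
  rnN <- renderNodule(v, 0.5, noiseSd = 200)
  expect_true(all(rnN$image@voxels >= -1024 & rnN$image@voxels <= 400))
})

test_that("an oversized nodule is rejected", {
  expect_error(renderNodule(sphereVol(20), 0, gridShape = c(32L, 32L, 32L)),
               "exceeds patch")
})

test_that("scan schedules respect the study's interval constraints", {
  set.seed(21)
  sched <- replicate(4000, sampleSchedule(), simplify = FALSE)
  expect_true(all(vapply(sched, function(t) t[1] == 0, TRUE)))
  gaps <- unlist(lapply(sched, diff))
  expect_true(all(gaps >= 30 & gaps <= 900))
  lens <- lengths(sched)
  expect_true(all(lens >= 2 & lens <= 11))
  spans <- vapply(sched, max, 0)
  expect_lte(max(spans), 2813)
  # median first-to-last span near one year, as in the emulated cohort
  expect_gt(median(spans), 250)
  expect_lt(median(spans), 500)
})

test_that("IA series have stochastically faster first-to-last VDT than non-IA", {
  set.seed(31)
  vdt1 <- replicate(200, {
    s <- sampleSeries(sampleGrowthParams("IA"), gridShape = rep(32L, 3))
    vdtScoreSeries(s)@invVdt
  })
  vdt0 <- replicate(200, {
    s <- sampleSeries(sampleGrowthParams("non-IA"), gridShape = rep(32L, 3))
    vdtScoreSeries(s)@invVdt
  })
  # inverse VDT larger (faster growth) for IA
  expect_lt(wilcox.test(vdt0, vdt1, alternative = "less")$p.value, 0.01)
})

test_that("mask-derived volumes agree with the analytic growth curve", {
  ser <- cleanGrowthSeries(dtDouble = 300, seed = 8)
  av <- attr(ser, "analyticVolumes")
  r <- sphereRad <- (3 * av / (4 * pi))^(1 / 3)
  expect_true(all(abs(volumes(ser) - av) < 4 * pi * r^2))
})

test_that("dataset generation hits the exact nodule-level split", {
  expect_identical(ViSTA:::splitCounts(351L, c(245, 37, 69) / 351),
                   c(245L, 37L, 69L))
  ds <- generateDataset(nSeries = 40, seed = 9, patchSize = 16L,
                        split = c(train = 28, val = 4, test = 8) / 40)
  expect_equal(unname(table(ds$split)[c("train", "val", "test")]),
               c(28L, 4L, 8L), ignore_attr = TRUE)
  # nodule-level: every scan of a series shares one split
  bySeries <- tapply(ds$manifest$split, ds$manifest$series_id,
                     function(x) length(unique(x)))
  expect_true(all(bySeries == 1))
  # a series id never appears in two splits
  expect_equal(anyDuplicated(unique(ds$manifest[c("series_id", "split")])$series_id), 0L)
})

test_that("the same seed reproduces the manifest byte for byte", {
  d1 <- generateDataset(nSeries = 12, seed = 5, patchSize = 16L)
  d2 <- generateDataset(nSeries = 12, seed = 5, patchSize = 16L)
  expect_identical(d1$manifest, d2$manifest)
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(d1$manifest, f1, row.names = FALSE)
  write.csv(d2$manifest, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("on-disk mode writes NIfTI volumes and a complete manifest", {
  dir <- tempfile("synthds")
  ds <- generateDataset(nSeries = 3, seed = 4, dir = dir,
                        gridShape = c(32L, 32L, 32L),
                        split = c(train = 1 / 3, val = 1 / 3, test = 1 / 3))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_named(man, c("series_id", "timepoint", "days", "image", "mask",
                      "volume_mm3", "label", "split"))
  expect_true(all(file.exists(file.path(dir, man$image))))
  expect_true(all(file.exists(file.path(dir, man$mask))))
  v <- readCTVolume(file.path(dir, man$image[1]))
  expect_s4_class(v, "CTVolume")
  expect_equal(dim(v@voxels), c(32, 32, 32))
  unlink(dir, recursive = TRUE)
})
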