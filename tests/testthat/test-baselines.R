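# VDT scoring and the static/recurrent counterparts.

test_that("VDT closed form: doubling identity and a hand-computed case", {
  r <- computeVDT(100, 200, 100)
  expect_equal(r@vdtDays, 100)
  expect_equal(r@invVdt, 1 / 100)
  # 365 * ln 2 / ln 1.5, evaluated independently at high precision
  r2 <- computeVDT(100, 150, 365)
  expect_equal(r2@vdtDays, 365 * log(2) / log(1.5), tolerance = 1e-12)
  expect_equal(r2@vdtDays, 623.96, tolerance = 1e-4)
  # no growth
  r3 <- computeVDT(80, 80, 200)
  expect_identical(r3@invVdt, 0)
  expect_identical(r3@vdtDays, Inf)
  expect_error(computeVDT(-1, 50, 10), "positive")
  expect_error(computeVDT(50, 50, 0), "positive")
})

test_that("VDT is antisymmetric under swapping the two volumes", {
  set.seed(23)
  for (i in 1:20) {
    v1 <- runif(1, 30, 500)
    v2 <- runif(1, 30, 500)
    dt <- runif(1, 30, 900)
    expect_equal(computeVDT(v1, v2, dt)@invVdt,
                 -computeVDT(v2, v1, dt)@invVdt, tolerance = 1e-12)
  }
  # shrinkage gives a negative score, ranking below all growers
  expect_lt(computeVDT(200, 100, 100)@invVdt, 0)
})

test_that("series VDT recovers the simulator's doubling time on clean data", {
  ser <- cleanGrowthSeries(dtDouble = 200, seed = 19)
  est <- vdtScoreSeries(ser)@vdtDays
  expect_lt(abs(est - 200) / 200, 0.10)   # within voxelization error
  # static series
  stat <- cleanGrowthSeries(dtDouble = Inf, seed = 20)
  expect_identical(vdtScoreSeries(stat)@invVdt, 0)
  # monotone shrinkage scores negative
  grow <- cleanGrowthSeries(dtDouble = 300, seed = 21)
  shrink <- new("FollowUpSeries", seriesId = "r", times = grow@times,
                patches = grow@patches,
                volumes = sort(grow@volumes, decreasing = TRUE),
                label = grow@label)
  expect_lt(vdtScoreSeries(shrink)@invVdt, 0)
})

test_that("cutoff rules classify as specified", {
  rule400 <- vdt400Rule()
  mk <- function(vdt) new("VDTResult", vdtDays = vdt,
                          invVdt = ifelse(is.finite(vdt), 1 / vdt, 0))
  expect_identical(vdtClassify(mk(399), rule400), "positive")
  expect_identical(vdtClassify(mk(401), rule400), "negative")
  expect_identical(vdtClassify(mk(Inf), rule400), "negative")
  yj <- new("CutoffRule", threshold = 1 / 500, direction = ">=",
            origin = "best_youden")
  expect_identical(vdtClassify(mk(400), yj), "positive")
  expect_identical(vdtClassify(mk(600), yj), "negative")
  expect_identical(vdtClassify(mk(Inf), yj), "negative")
})

test_that("a Youden cutoff from a separable set classifies it perfectly", {
  scores <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  rule <- bestYoudenCutoff(scores, labels)
  expect_equal(attr(rule, "youden"), 1)
  pred <- as.numeric(scores >= rule@threshold)
  expect_identical(pred, labels)
})

test_that("the static CNN scores any time point regardless of training policy", {
  d <- tinyDataset(n = 12, seed = 3, patchSize = 16L)
  mod <- cnnScorer(patchSize = 16L, channels = c(4L, 8L), seed = 1)
  mod <- trainModel(mod, d, trainConfig(epochs = 2, seed = 1,
                                        trainPolicy = "first_only"))
  ser <- d$test[[1]]
  pLast <- predictIA(mod, ser, at = "last")
  pFirst <- predictIA(mod, ser, at = "first")
  expect_true(pLast@pIA >= 0 && pLast@pIA <= 1)
  expect_identical(pFirst@pIA, pFirst@perStep[1])
  expect_identical(pLast@pIA, pLast@perStep[nTimepoints(ser)])
})

test_that("all-points training uses every scan as an independent sample", {
  d <- tinyDataset(n = 12, seed = 4, patchSize = 16L)
  nScans <- sum(vapply(d$train, nTimepoints, 0L))
  mod <- cnnScorer(patchSize = 16L, channels = c(4L, 8L), seed = 1)
  mod <- trainModel(mod, d, trainConfig(epochs = 1, seed = 1,
                                        trainPolicy = "all_points"))
  h <- attr(mod, "history")
  expect_s3_class(h, "data.frame")
  # the training-sample count equals the total scan count of the split
  pol <- "all_points"
  plist <- unlist(lapply(d$train, patches), recursive = FALSE)
  expect_length(plist, nScans)
})

test_that("training on the last scan beats training on the first scan", {
  # later scans carry more diagnostic information (growth has happened,
  # solid transformation has progressed)
  ds <- generateDataset(nSeries = 120, seed = 42, patchSize = 16L)
  d <- splitDataset(ds)
  yTest <- vapply(d$test, function(s) as.numeric(noduleLabel(s) == "IA"), 0)
  aucAt <- function(pol, at, seed) {
    mod <- cnnScorer(patchSize = 16L, channels = c(4L, 8L), seed = seed)
    mod <- trainModel(mod, d, trainConfig(epochs = 8, seed = seed,
                                          trainPolicy = pol))
    aucScore(vapply(d$test, function(s) predictIA(mod, s, at = at)@pIA, 0),
             yTest)
  }
  diffs <- vapply(1:5, function(sd) {
    aucAt("last_only", "last", sd) - aucAt("first_only", "first", sd)
  }, 0)
  expect_gte(median(diffs), 0)
})

test_that("the recurrent baseline is blind to scan intervals but ViSTA is not", {
  lst <- cnnLstmModel(patchSize = 8L, channels = c(3L, 4L), seed = 2)
  ser <- makePatchSeries(4, seed = 30)
  stretched <- new("FollowUpSeries", seriesId = "st",
                   times = ser@times * 3, patches = ser@patches,
                   volumes = ser@volumes, label = ser@label)
  expect_identical(predictIA(lst, ser)@pIA, predictIA(lst, stretched)@pIA)
  # single-step series still yields a probability
  one <- new("FollowUpSeries", seriesId = "o", times = 0,
             patches = ser@patches[1], volumes = ser@volumes[1],
             label = ser@label)
  p1 <- predictIA(lst, one)@pIA
  expect_true(p1 >= 0 && p1 <= 1)
  # ViSTA's exponential-decay attention sees the rescaled gaps
  vis <- tinyVista(seed = 2)
  expect_gt(abs(predictIA(vis, ser)@pIA - predictIA(vis, stretched)@pIA), 0)
})

test_that("the recurrent module outweighs the SimTA module at equal width", {
  v <- vistaModel(patchSize = 16L, channels = c(4L, 8L), seed = 1)
  l <- cnnLstmModel(patchSize = 16L, channels = c(4L, 8L), seed = 1)
  expect_gt(countParams(l, includeBackbone = FALSE),
            countParams(v, includeBackbone = FALSE))
})
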