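# Metrics, cutoff selection, schedule, training loop behavior.

bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

bruteYouden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  J <- sapply(cand, function(th) {
    mean(scores[labels == 1] >= th) + mean(scores[labels == 0] < th) - 1
  })
  list(threshold = cand[which.max(J)], J = max(J))
}

test_that("AUC equals pairwise concordance with ties counted one half", {
  expect_equal(aucScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(aucScore(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(aucScore(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(aucScore(1:4, c(1, 1, 1, 1)), "AUC undefined")
  set.seed(33)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (sum(y) == 0 || sum(y) == n) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # heavy ties
    expect_equal(aucScore(s, y), bruteAUC(s, y), tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals exhaustive search and breaks ties downward", {
  set.seed(34)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (sum(y) == 0 || sum(y) == n) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    rule <- bestYoudenCutoff(s, y)
    bf <- bruteYouden(s, y)
    expect_equal(attr(rule, "youden"), bf$J, tolerance = 1e-12)
    # the returned threshold attains the brute-force optimum
    Jat <- mean(s[y == 1] >= rule@threshold) +
      mean(s[y == 0] < rule@threshold) - 1
    expect_equal(Jat, bf$J, tolerance = 1e-12)
  }
  # all scores equal: no threshold separates anything
  r0 <- bestYoudenCutoff(rep(0.3, 8), c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(attr(r0, "youden"), 0)
  expect_error(bestYoudenCutoff(1:3, c(1, 1, 1)), "one class")
})

test_that("thresholded metrics are internally consistent and report NA when undefined", {
  set.seed(35)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (sum(y) == 0 || sum(y) == n) next
    s <- runif(n)
    th <- runif(1)
    r <- thresholdedMetrics(s, y, th)
    cc <- r@counts
    expect_equal(sum(cc), n)
    expect_equal(r@accuracy, (cc["TP"] + cc["TN"]) / n, ignore_attr = TRUE)
    if (!is.na(r@precision)) {
      expect_equal(r@precision, cc["TP"] / (cc["TP"] + cc["FP"]),
                   ignore_attr = TRUE)
    }
    if (!is.na(r@f1)) {
      expect_equal(r@f1, 2 * r@precision * r@sensitivity /
                     (r@precision + r@sensitivity))
    }
    expect_equal(r@roc$fpr[1], 0)
    expect_equal(r@roc$tpr[nrow(r@roc)], 1)
    expect_true(all(diff(r@roc$fpr) >= 0) && all(diff(r@roc$tpr) >= 0))
  }
  # no predicted positives: precision undefined, not zero
  r <- thresholdedMetrics(c(0.1, 0.2, 0.3), c(0, 1, 1), threshold = 2)
  expect_true(is.na(r@precision))
  expect_true(is.na(r@f1))
  expect_equal(r@sensitivity, 0)
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  expect_equal(f1Score(0.744, 0.906), 0.817, tolerance = 5e-4)
  expect_equal(f1Score(0.714, 0.156), 0.256, tolerance = 2e-3)
  expect_equal(f1Score(0.6, 0.6), 0.6)       # identity at equal rates
  expect_true(is.na(f1Score(0, 0)))
})

test_that("the cosine schedule hits its endpoints and midpoint", {
  expect_equal(cosineLR(0, 100), 1e-3)
  expect_equal(cosineLR(100, 100), 1e-6)
  expect_equal(cosineLR(99, 100, 1e-3, 1e-6), 1e-6,
               tolerance = 1e-3)   # final epoch within one step of the floor
  expect_equal(cosineLR(50, 100), 1e-6 + (1e-3 - 1e-6) / 2)  # ~5.005e-4
})

test_that("confusion reconstruction from printed rates is exact on round counts", {
  # sens 29/32, prec 29/39 in a 32/37 test set
  r <- confusionFromRates(0.906, 0.744, 32, 37)
  expect_equal(unname(r@counts), c(29L, 10L, 27L, 3L))
  expect_equal(r@accuracy, 56 / 69, tolerance = 1e-12)
})

test_that("a short training run reduces the loss and is reproducible", {
  d <- tinyDataset(n = 16, seed = 12, patchSize = 16L)
  cfg <- trainConfig(epochs = 5, seed = 2, batchSize = 4)
  mod <- vistaModel(patchSize = 16L, channels = c(4L, 8L), nLayers = 1L,
                    seed = 2)
  t1 <- trainModel(mod, d, cfg)
  h1 <- attr(t1, "history")
  expect_lt(h1$loss[5], h1$loss[1])
  expect_equal(h1$lr[1], 1e-3)
  # identical config and seed reproduce the history exactly
  t2 <- trainModel(mod, d, cfg)
  expect_identical(h1, attr(t2, "history"))
  expect_identical(predictIA(t1, d$test[[1]])@pIA,
                   predictIA(t2, d$test[[1]])@pIA)
  expect_error(trainModel(mod, list(train = list(), val = list()), cfg),
               "empty training split")
})

test_that("the comparison table carries model rows plus reader reference rows", {
  scores <- c(0.2, 0.8, 0.3, 0.9, 0.1, 0.7)
  y <- c(0, 1, 0, 1, 0, 1)
  rep1 <- thresholdedMetrics(scores, y, 0.5)
  tab <- compareReport(list(vista = rep1))
  expect_equal(nrow(tab), 4)    # one model + three readers
  expect_setequal(tab$method, c("vista", "Senior", "Junior 1", "Junior 2"))
  sr <- tab[tab$method == "Senior", ]
  expect_equal(unlist(sr[c("accuracy", "precision", "sensitivity", "f1")]),
               c(0.855, 0.824, 0.875, 0.848), ignore_attr = TRUE)
  # model-only table when no reference set is supplied
  tab2 <- compareReport(list(vista = rep1), radiologists = NULL)
  expect_equal(nrow(tab2), 1)
  # a perfect scorer's ROC passes through (0, 1)
  rocp <- thresholdedMetrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)@roc
  expect_true(any(rocp$fpr == 0 & rocp$tpr == 1))
  # CSV export
  f <- tempfile(fileext = ".csv")
  compareReport(list(vista = rep1), csvFile = f)
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), 4)
})
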