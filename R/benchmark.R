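# Scaled-down benchmark: the full study design (351 nodules, 245/37/69
# nodule-level split) on synthetic follow-up series, with a 20-epoch budget
# per model so the whole comparison runs on one CPU.

#' Split a simulated dataset into train/validation/test lists
#'
#' @param ds result of [generateDataset()] (in-memory mode).
#' @return list with `train`, `val`, `test` lists of
#'   [FollowUpSeries-class].
#' @export
splitDataset <- function(ds) {
  bySplit <- split(seq_along(ds$series), ds$split[vapply(ds$series,
                                                         seriesId, "")])
  lapply(list(train = "train", val = "val", test = "test"), function(s) {
    ds$series[bySplit[[s]]]
  })
}

.testScores <- function(model, test, ...) {
  vapply(test, function(s) predictIA(model, s, ...)@pIA, 0)
}

#' Train and evaluate all methods on the synthetic benchmark
#'
#' Generates the default synthetic dataset (351 series, 245/37/69
#' nodule-level split), trains ViSTA and the requested counterparts for each
#' training seed, picks each model's decision threshold by the best Youden
#' index on the validation split, and evaluates on the held-out test split.
#' The VDT baseline is scored as `1/VDT` between the first and last scan,
#' with both the fixed 400-day cutoff and the validation-Youden cutoff.
#'
#' @param dataSeed seed of the synthetic dataset (default 42).
#' @param trainSeeds integer vector; one full training run per seed.
#' @param nSeries dataset size (default 351).
#' @param epochs training epochs per model (default 20).
#' @param methods subset of `"vista"`, `"cnn_lstm"`, `"cnn_last"`,
#'   `"cnn_first"`, `"vdt"`.
#' @param patchSize,channels model geometry.
#' @param verbose print progress.
#' @return data.frame with one row per (method, seed): test AUC, accuracy,
#'   precision, sensitivity, F1 at the validation-Youden threshold. The
#'   [MetricsReport-class] objects of the last seed are attached as
#'   attribute `"reports"`.
#' @export
runBenchmark <- function(dataSeed = 42L, trainSeeds = 1:5, nSeries = 351L,
                         epochs = 20L,
                         methods = c("vista", "cnn_lstm", "cnn_last"),
                         patchSize = 32L, channels = c(4L, 8L, 16L, 16L),
                         verbose = FALSE) {
  ds <- generateDataset(nSeries = nSeries, seed = dataSeed,
                        patchSize = patchSize)
  data <- splitDataset(ds)
  yTest <- vapply(data$test, .seriesY, 0)
  yVal <- vapply(data$val, .seriesY, 0)
  rows <- list()
  reports <- list()
  evalScorer <- function(valScores, testScores) {
    rule <- bestYoudenCutoff(valScores, yVal)
    thresholdedMetrics(testScores, yTest, rule@threshold)
  }
  for (seed in trainSeeds) {
    for (m in methods) {
      t0 <- Sys.time()
      if (m == "vdt") {
        inv <- function(ss) vapply(ss, function(s) vdtScoreSeries(s)@invVdt, 0)
        rpt <- evalScorer(inv(data$val), inv(data$test))
        # fixed 400-day rule as the alternative cutoff policy
        pred400 <- vapply(data$test, function(s) {
          vdtClassify(vdtScoreSeries(s), vdt400Rule()) == "positive"
        }, TRUE)
        rep400 <- thresholdedMetrics(as.numeric(pred400), yTest, 0.5)
        rep400@auc <- rpt@auc   # same ranking score, different cutoff
        reports[["vdt_400"]] <- rep400
      } else if (m == "vista") {
        mod <- vistaModel(patchSize = patchSize, channels = channels,
                          seed = seed)
        mod <- trainModel(mod, data, trainConfig(epochs = epochs, seed = seed,
                                                 verbose = verbose))
        rpt <- evalScorer(.testScores(mod, data$val),
                          .testScores(mod, data$test))
      } else if (m == "cnn_lstm") {
        mod <- cnnLstmModel(patchSize = patchSize, channels = channels,
                            seed = seed)
        mod <- trainModel(mod, data, trainConfig(epochs = epochs, seed = seed,
                                                 verbose = verbose))
        rpt <- evalScorer(.testScores(mod, data$val),
                          .testScores(mod, data$test))
      } else {
        pol <- if (m == "cnn_last") "last_only" else "first_only"
        at <- if (m == "cnn_last") "last" else "first"
        mod <- cnnScorer(patchSize = patchSize, channels = channels,
                         seed = seed)
        mod <- trainModel(mod, data, trainConfig(epochs = epochs, seed = seed,
                                                 trainPolicy = pol,
                                                 verbose = verbose))
        rpt <- evalScorer(.testScores(mod, data$val, at = at),
                          .testScores(mod, data$test, at = at))
      }
      reports[[m]] <- rpt
      rows[[length(rows) + 1]] <- data.frame(
        method = m, seed = seed, auc = rpt@auc, accuracy = rpt@accuracy,
        precision = rpt@precision, sensitivity = rpt@sensitivity,
        f1 = rpt@f1, stringsAsFactors = FALSE
      )
      if (verbose) {
        message(sprintf("%s seed %d: AUC %.3f (%.1f s)", m, seed, rpt@auc,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
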