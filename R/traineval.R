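# Training harness (AdamW + cosine schedule, binary cross-entropy on the
# final-step probability, best-validation-AUC model selection) and the
# evaluation stack: AUC with midrank tie handling, thresholded metrics,
# Youden cutoff selection, ROC export and the model/reader comparison table.

#' Training configuration
#'
#' Defaults follow the common AdamW recipe used for the study models:
#' 100 epochs, batch size 32, cosine learning-rate decay from 1e-3 to 1e-6,
#' weight decay 0.01, dropout 0.2.
#'
#' @param epochs number of epochs.
#' @param batchSize series (or patches, for the static CNN) per update.
#' @param lrMax,lrMin cosine schedule endpoints.
#' @param weightDecay decoupled AdamW weight decay.
#' @param seed integer seed controlling shuffling and dropout.
#' @param selection `"final"` (default: the model after the last epoch, where
#'   the cosine schedule has annealed the step size to its floor) or
#'   `"best_val_auc"` (keep the epoch with the highest validation AUC —
#'   unreliable with small validation splits, where the per-epoch AUC is
#'   noisy enough that its argmax often lands on an undertrained epoch).
#' @param trainPolicy for [CNNScorer-class]: `"last_only"`, `"first_only"`
#'   or `"all_points"`.
#' @param evalAt for [CNNScorer-class]: `"last"` or `"first"` time point
#'   used for validation scoring.
#' @param auxWeight weight of an optional per-step auxiliary loss on the
#'   non-final steps (0 = off).
#' @param clipNorm global L2 gradient-norm clip per update (`Inf` disables).
#' @param verbose print per-epoch progress.
#' @return named list.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 32L, lrMax = 1e-3,
                        lrMin = 1e-6, weightDecay = 0.01, seed = 1L,
                        selection = c("final", "best_val_auc"),
                        trainPolicy = c("last_only", "first_only",
                                        "all_points"),
                        evalAt = NULL, auxWeight = 0, clipNorm = 1,
                        verbose = FALSE) {
  stopifnot(epochs >= 1, lrMin <= lrMax)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lrMax = lrMax, lrMin = lrMin, weightDecay = weightDecay,
       seed = as.integer(seed), selection = match.arg(selection),
       trainPolicy = match.arg(trainPolicy), evalAt = evalAt,
       auxWeight = auxWeight, clipNorm = clipNorm, verbose = verbose)
}

.labels01 <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels)
  }
  as.numeric(as.character(labels) == "IA")
}

.seriesY <- function(series) as.numeric(noduleLabel(series) == "IA")

#' Area under the ROC curve
#'
#' Midrank implementation: equals the probability that a random positive
#' outscores a random negative, with ties counted 1/2 (identical to the
#' trapezoidal area under the empirical ROC).
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels 0/1, logical, or `"IA"`/`"non-IA"` (IA positive).
#' @return numeric(1) in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  y <- .labels01(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class missing")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams aucScore
#' @return data.frame with non-decreasing `fpr`, `tpr` from (0,0) to (1,1).
#' @export
rocPoints <- function(scores, labels) {
  y <- .labels01(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)   # one point per distinct score
  tpr <- cumsum(y)[keep] / sum(y)
  fpr <- cumsum(1 - y)[keep] / sum(1 - y)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Harmonic mean of precision and sensitivity
#' @param precision,sensitivity numeric in \[0, 1\].
#' @return the F1 score, `NA` if both are zero or either is `NA`.
#' @export
f1Score <- function(precision, sensitivity) {
  ifelse(is.na(precision) | is.na(sensitivity) |
           (precision + sensitivity) == 0, NA_real_,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Reconstruct a confusion matrix from printed rates
#'
#' Given a reported sensitivity and precision together with the class sizes
#' of a test set, recovers the integer confusion counts (rounding TP and
#' TP+FP to the nearest integers) and the implied accuracy/F1. Used for
#' internal-consistency checks of published results tables.
#'
#' @param sensitivity,precision reported rates in \[0, 1\].
#' @param nPos,nNeg positives/negatives in the evaluated set.
#' @return a [MetricsReport-class] (no ROC, `auc = NA`).
#' @export
confusionFromRates <- function(sensitivity, precision, nPos, nNeg) {
  TP <- round(sensitivity * nPos)
  FP <- round(TP / precision) - TP
  FN <- nPos - TP
  TN <- nNeg - FP
  metricsFromCounts(TP, FP, TN, FN, threshold = NA_real_)
}

metricsFromCounts <- function(TP, FP, TN, FN, threshold, auc = NA_real_,
                              roc = data.frame(fpr = numeric(0),
                                               tpr = numeric(0))) {
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- sdiv(TP, TP + FP)
  sens <- sdiv(TP, TP + FN)
  spec <- sdiv(TN, TN + FP)
  new("MetricsReport",
      auc = auc,
      accuracy = sdiv(TP + TN, TP + FP + TN + FN),
      precision = prec, sensitivity = sens, specificity = spec,
      f1 = f1Score(prec, sens),
      youden = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1,
      threshold = threshold,
      counts = c(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN)),
      roc = roc)
}

#' Thresholded and threshold-free evaluation of a scorer
#'
#' Positive iff `score >= threshold`. Zero-denominator metrics are `NA`.
#'
#' @inheritParams aucScore
#' @param threshold decision cutoff.
#' @return a [MetricsReport-class] including AUC and ROC points when both
#'   classes are present.
#' @export
thresholdedMetrics <- function(scores, labels, threshold) {
  y <- .labels01(labels)
  pred <- as.numeric(scores >= threshold)
  TP <- sum(pred == 1 & y == 1)
  FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0)
  FN <- sum(pred == 0 & y == 1)
  both <- sum(y == 1) > 0 && sum(y == 0) > 0
  metricsFromCounts(TP, FP, TN, FN, threshold,
                    auc = if (both) aucScore(scores, y) else NA_real_,
                    roc = if (both) rocPoints(scores, y) else
                      data.frame(fpr = numeric(0), tpr = numeric(0)))
}

#' Cutoff maximizing the Youden index
#'
#' Evaluates `J = sensitivity + specificity - 1` at every candidate
#' threshold (midpoints between adjacent distinct sorted scores plus
#' `-Inf`/`+Inf`) and returns the maximizer; ties break toward the smallest
#' threshold.
#'
#' @inheritParams aucScore
#' @return a [CutoffRule-class] with origin `"best_youden"`; the attained
#'   index is attached as attribute `"youden"`.
#' @export
bestYoudenCutoff <- function(scores, labels) {
  y <- .labels01(labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("Youden cutoff undefined: one class missing")
  }
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  J <- vapply(cand, function(th) {
    sens <- sum(scores >= th & y == 1) / sum(y == 1)
    spec <- sum(scores < th & y == 0) / sum(y == 0)
    sens + spec - 1
  }, 0)
  best <- which(J >= max(J) - 1e-12)[1]   # smallest threshold among ties
  rule <- new("CutoffRule", threshold = cand[best], direction = ">=",
              origin = "best_youden")
  attr(rule, "youden") <- J[best]
  rule
}

#' Reference reader performance on the original test cohort
#'
#' Fixed operating points of the three radiologists (one senior, two
#' junior) from the observer study on the 69-series clinical test set,
#' bundled as plotting/comparison constants. These are reference values,
#' not outputs of this package.
#'
#' @return data.frame with one row per reader.
#' @export
radiologistReference <- function() {
  data.frame(
    method = c("Senior", "Junior 1", "Junior 2"),
    auc = NA_real_,
    accuracy = c(0.855, 0.754, 0.710),
    precision = c(0.824, 0.742, 0.731),
    sensitivity = c(0.875, 0.719, 0.594),
    f1 = c(0.848, 0.730, 0.655),
    source = "reference",
    stringsAsFactors = FALSE
  )
}

#' Comparison table (and optional ROC figure) across methods
#'
#' Assembles one row per evaluated method (AUC, accuracy, precision,
#' sensitivity, F1) plus the bundled reader reference rows, optionally
#' writing a CSV and an ROC figure on which readers appear as single
#' operating points.
#'
#' @param reports named list of [MetricsReport-class] objects.
#' @param radiologists data.frame of reference operating points (or `NULL`);
#'   default [radiologistReference()].
#' @param csvFile,rocFile optional output paths.
#' @return the comparison data.frame, invisibly when files are written.
#' @export
compareReport <- function(reports, radiologists = radiologistReference(),
                          csvFile = NULL, rocFile = NULL) {
  stopifnot(length(reports) >= 1)
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, auc = r@auc, accuracy = r@accuracy,
               precision = r@precision, sensitivity = r@sensitivity,
               f1 = r@f1, source = "model", stringsAsFactors = FALSE)
  }))
  tab <- rbind(rows, radiologists)
  if (!is.null(csvFile)) utils::write.csv(tab, csvFile, row.names = FALSE)
  if (!is.null(rocFile) && capabilities("png")) {
    grDevices::png(rocFile, width = 720, height = 720)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "gray",
                   xlab = "False positive rate", ylab = "Sensitivity",
                   main = "ROC, models vs readers")
    cols <- grDevices::hcl.colors(max(3, length(reports)), "Dark 3")
    for (i in seq_along(reports)) {
      roc <- reports[[i]]@roc
      if (nrow(roc)) graphics::lines(roc$fpr, roc$tpr, col = cols[i], lwd = 2)
    }
    if (!is.null(radiologists) && nrow(radiologists)) {
      # reader operating points: false-positive rate recovered from the
      # printed sensitivity/precision and the reference class sizes (32/37)
      fpr <- vapply(seq_len(nrow(radiologists)), function(i) {
        r <- confusionFromRates(radiologists$sensitivity[i],
                                radiologists$precision[i], 32, 37)
        1 - r@specificity
      }, 0)
      graphics::points(fpr, radiologists$sensitivity, pch = 17)
      graphics::text(fpr, radiologists$sensitivity, radiologists$method,
                     pos = 4, cex = 0.8)
    }
    graphics::legend("bottomright", legend = names(reports), col =
                       cols[seq_along(reports)], lwd = 2, bty = "n")
  }
  if (is.null(csvFile) && is.null(rocFile)) tab else invisible(tab)
}

# --- training loops --------------------------------------------------------

bceFromLogit <- function(z, y) {
  # numerically stable binary cross-entropy
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

# pre-flattened split for one-pass validation scoring each epoch
.packSeries <- function(sers) {
  if (length(sers) == 0) return(NULL)
  list(X = patchMatrix(unlist(lapply(sers, patches), recursive = FALSE)),
       lens = vapply(sers, nTimepoints, 0L),
       times = lapply(sers, seriesTimes),
       y = vapply(sers, .seriesY, 0),
       patchSize = dim(patches(sers[[1]])[[1]])[1])
}

.packAUC <- function(pack, scorer) {
  if (is.null(pack) || sum(pack$y) == 0 || sum(1 - pack$y) == 0) {
    return(NA_real_)
  }
  aucScore(scorer(pack), pack$y)
}

.vistaPackScores <- function(model, pack) {
  feat <- encoderForward(model@encoder,
                         batchFromMatrix(pack$X, pack$patchSize,
                                         seq_len(ncol(pack$X))),
                         train = FALSE)$feat
  offs <- cumsum(c(0L, pack$lens))
  vapply(seq_along(pack$lens), function(k) {
    f <- vistaSequenceForward(model,
                              feat[(offs[k] + 1L):offs[k + 1L], ,
                                   drop = FALSE],
                              pack$times[[k]])
    f$perStep[length(f$perStep)]
  }, 0)
}

.lstmPackScores <- function(model, pack) {
  feat <- encoderForward(model@encoder,
                         batchFromMatrix(pack$X, pack$patchSize,
                                         seq_len(ncol(pack$X))),
                         train = FALSE)$feat
  offs <- cumsum(c(0L, pack$lens))
  vapply(seq_along(pack$lens), function(k) {
    h <- lstmForward(model@lstm,
                     feat[(offs[k] + 1L):offs[k + 1L], , drop = FALSE])$h
    sigmoidv(sum(h * model@head$w) + model@head$b)
  }, 0)
}

.cnnPackScores <- function(model, pack, at) {
  offs <- cumsum(c(0L, pack$lens))
  sel <- if (at == "first") offs[-length(offs)] + 1L else offs[-1L]
  feat <- encoderForward(model@encoder,
                         batchFromMatrix(pack$X, pack$patchSize, sel),
                         train = FALSE)$feat
  sigmoidv(drop(feat %*% model@head$w) + model@head$b)
}

#' @describeIn trainModel ViSTA: per batch, all patches of the batch series
#'   are encoded jointly, the SimTA stack runs per series, and the
#'   binary cross-entropy of the final-step probability is minimized.
#' @export
setMethod("trainModel", "VistaModel", function(model, data, cfg) {
  if (length(data$train) == 0) stop("empty training split")
  set.seed(cfg$seed)
  params <- list(encoder = model@encoder$stages, simta = model@simta,
                 head = model@head)
  opt <- adamwInit(params)
  hist <- data.frame()
  best <- list(auc = -Inf, params = params, state = model@encoder$state)
  y <- vapply(data$train, .seriesY, 0)
  bigX <- patchMatrix(unlist(lapply(data$train, patches), recursive = FALSE))
  ps <- model@config$patchSize
  valPack <- .packSeries(data$val)
  lensAll <- vapply(data$train, nTimepoints, 0L)
  offAll <- cumsum(c(0L, lensAll))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosineLR(epoch - 1, cfg$epochs, cfg$lrMax, cfg$lrMin)
    idx <- sample(length(data$train))
    losses <- numeric(0)
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batchSize))) {
      B <- length(b)
      sel <- unlist(lapply(b, function(k) (offAll[k] + 1L):offAll[k + 1L]))
      model@encoder$stages <- params$encoder
      ef <- encoderForward(model@encoder, batchFromMatrix(bigX, ps, sel),
                           train = TRUE)
      model@encoder$state <- ef$state
      offs <- cumsum(c(0L, lensAll[b]))
      dfeat <- ef$feat * 0
      gsim <- zeroLike(params$simta)
      ghead <- zeroLike(params$head)
      model@simta <- params$simta
      model@head <- params$head
      lossB <- 0
      for (k in seq_len(B)) {
        rows <- (offs[k] + 1L):offs[k + 1L]
        ser <- data$train[[b[k]]]
        fwd <- vistaSequenceForward(model, ef$feat[rows, , drop = FALSE],
                                    seriesTimes(ser), train = TRUE)
        Tn <- length(fwd$logits)
        yk <- y[b[k]]
        lossB <- lossB + bceFromLogit(fwd$logits[Tn], yk) / B
        dlog <- numeric(Tn)
        dlog[Tn] <- (fwd$perStep[Tn] - yk) / B
        if (cfg$auxWeight > 0 && Tn > 1) {
          dlog[-Tn] <- cfg$auxWeight * (fwd$perStep[-Tn] - yk) /
            ((Tn - 1) * B)
          lossB <- lossB + cfg$auxWeight *
            mean(bceFromLogit(fwd$logits[-Tn], yk)) / B
        }
        bk <- vistaSequenceBackward(model, fwd, dlog)
        dfeat[rows, ] <- bk$dfeat
        gsim <- addTrees(gsim, bk$simta)
        ghead <- addTrees(ghead, bk$head)
      }
      eb <- encoderBackward(model@encoder, ef$caches, dfeat)
      if (!is.finite(lossB)) stop("non-finite training loss")
      upd <- adamwStep(params,
                       clipTree(list(encoder = eb$grads, simta = gsim,
                                     head = ghead), cfg$clipNorm),
                       opt, lr, cfg$weightDecay)
      params <- upd$params
      opt <- upd$state
      losses <- c(losses, lossB)
    }
    model@encoder$stages <- params$encoder
    model@simta <- params$simta
    model@head <- params$head
    vauc <- .packAUC(valPack, function(p) .vistaPackScores(model, p))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   loss = mean(losses), val_auc = vauc))
    if (cfg$verbose) {
      message(sprintf("epoch %d: loss %.4f, val AUC %s", epoch,
                      mean(losses), format(vauc, digits = 3)))
    }
    if (!is.na(vauc) && vauc > best$auc) {
      best <- list(auc = vauc, params = params, state = model@encoder$state)
    }
  }
  if (cfg$selection == "best_val_auc" && is.finite(best$auc)) {
    params <- best$params
    model@encoder$state <- best$state
  }
  model@encoder$stages <- params$encoder
  model@simta <- params$simta
  model@head <- params$head
  attr(model, "history") <- hist
  model
})

#' @describeIn trainModel static CNN: training samples are single patches
#'   selected by `cfg$trainPolicy` (`last_only`, `first_only`, or
#'   `all_points`, each scan carrying its series label).
#' @export
setMethod("trainModel", "CNNScorer", function(model, data, cfg) {
  if (length(data$train) == 0) stop("empty training split")
  set.seed(cfg$seed)
  pol <- cfg$trainPolicy
  pick <- function(s) {
    ps <- patches(s)
    switch(pol,
           first_only = ps[1],
           last_only = ps[length(ps)],
           all_points = ps)
  }
  plist <- unlist(lapply(data$train, pick), recursive = FALSE)
  y <- unlist(lapply(data$train, function(s) {
    rep(.seriesY(s), length(pick(s)))
  }))
  evalAt <- cfg$evalAt %||% (if (pol == "first_only") "first" else "last")
  model@config$trainPolicy <- pol
  params <- list(encoder = model@encoder$stages, head = model@head)
  opt <- adamwInit(params)
  hist <- data.frame()
  best <- list(auc = -Inf, params = params, state = model@encoder$state)
  drp <- model@config$dropout
  bigX <- patchMatrix(plist)
  ps <- model@config$patchSize
  valPack <- .packSeries(data$val)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosineLR(epoch - 1, cfg$epochs, cfg$lrMax, cfg$lrMin)
    idx <- sample(length(plist))
    losses <- numeric(0)
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batchSize))) {
      model@encoder$stages <- params$encoder
      ef <- encoderForward(model@encoder, batchFromMatrix(bigX, ps, b),
                           train = TRUE)
      model@encoder$state <- ef$state
      feat <- ef$feat
      m <- if (drp > 0) dropoutMask(feat, drp) else NULL
      fd <- applyMask(feat, m)
      z <- drop(fd %*% params$head$w) + params$head$b
      p <- sigmoidv(z)
      yb <- y[b]
      lossB <- mean(bceFromLogit(z, yb))
      if (!is.finite(lossB)) stop("non-finite training loss")
      dz <- (p - yb) / length(b)
      ghead <- list(w = drop(crossprod(fd, dz)), b = sum(dz))
      dfeat <- applyMask(outer(dz, params$head$w), m)
      eb <- encoderBackward(model@encoder, ef$caches, dfeat)
      upd <- adamwStep(params,
                       clipTree(list(encoder = eb$grads, head = ghead),
                                cfg$clipNorm),
                       opt, lr, cfg$weightDecay)
      params <- upd$params
      opt <- upd$state
      losses <- c(losses, lossB)
    }
    model@encoder$stages <- params$encoder
    model@head <- params$head
    vauc <- .packAUC(valPack, function(p) .cnnPackScores(model, p, evalAt))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   loss = mean(losses), val_auc = vauc))
    if (!is.na(vauc) && vauc > best$auc) {
      best <- list(auc = vauc, params = params, state = model@encoder$state)
    }
  }
  if (cfg$selection == "best_val_auc" && is.finite(best$auc)) {
    params <- best$params
    model@encoder$state <- best$state
  }
  model@encoder$stages <- params$encoder
  model@head <- params$head
  attr(model, "history") <- hist
  model
})

#' @describeIn trainModel CNN+LSTM: per batch the series' patches are
#'   encoded jointly and the recurrence is unrolled per series; scan times
#'   are never consumed.
#' @export
setMethod("trainModel", "CNNLSTMModel", function(model, data, cfg) {
  if (length(data$train) == 0) stop("empty training split")
  set.seed(cfg$seed)
  params <- list(encoder = model@encoder$stages, lstm = model@lstm,
                 head = model@head)
  opt <- adamwInit(params)
  hist <- data.frame()
  best <- list(auc = -Inf, params = params, state = model@encoder$state)
  y <- vapply(data$train, .seriesY, 0)
  drp <- model@config$dropout
  bigX <- patchMatrix(unlist(lapply(data$train, patches), recursive = FALSE))
  ps <- model@config$patchSize
  valPack <- .packSeries(data$val)
  lensAll <- vapply(data$train, nTimepoints, 0L)
  offAll <- cumsum(c(0L, lensAll))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosineLR(epoch - 1, cfg$epochs, cfg$lrMax, cfg$lrMin)
    idx <- sample(length(data$train))
    losses <- numeric(0)
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batchSize))) {
      B <- length(b)
      sel <- unlist(lapply(b, function(k) (offAll[k] + 1L):offAll[k + 1L]))
      model@encoder$stages <- params$encoder
      ef <- encoderForward(model@encoder, batchFromMatrix(bigX, ps, sel),
                           train = TRUE)
      model@encoder$state <- ef$state
      offs <- cumsum(c(0L, lensAll[b]))
      dfeat <- ef$feat * 0
      glstm <- zeroLike(params$lstm)
      ghead <- zeroLike(params$head)
      lossB <- 0
      for (k in seq_len(B)) {
        rows <- (offs[k] + 1L):offs[k + 1L]
        fwd <- lstmForward(params$lstm, ef$feat[rows, , drop = FALSE])
        m <- if (drp > 0) dropoutMask(fwd$h, drp) else NULL
        hd <- applyMask(fwd$h, m)
        z <- sum(hd * params$head$w) + params$head$b
        p <- sigmoidv(z)
        lossB <- lossB + bceFromLogit(z, y[b[k]]) / B
        dz <- (p - y[b[k]]) / B
        ghead$w <- ghead$w + dz * hd
        ghead$b <- ghead$b + dz
        dh <- applyMask(dz * params$head$w, m)
        bk <- lstmBackward(params$lstm, fwd$cache, dh)
        glstm <- addTrees(glstm, bk$grads)
        dfeat[rows, ] <- bk$dx
      }
      if (!is.finite(lossB)) stop("non-finite training loss")
      eb <- encoderBackward(model@encoder, ef$caches, dfeat)
      upd <- adamwStep(params,
                       clipTree(list(encoder = eb$grads, lstm = glstm,
                                     head = ghead), cfg$clipNorm),
                       opt, lr, cfg$weightDecay)
      params <- upd$params
      opt <- upd$state
      losses <- c(losses, lossB)
    }
    model@encoder$stages <- params$encoder
    model@lstm <- params$lstm
    model@head <- params$head
    vauc <- .packAUC(valPack, function(p) .lstmPackScores(model, p))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   loss = mean(losses), val_auc = vauc))
    if (!is.na(vauc) && vauc > best$auc) {
      best <- list(auc = vauc, params = params, state = model@encoder$state)
    }
  }
  if (cfg$selection == "best_val_auc" && is.finite(best$auc)) {
    params <- best$params
    model@encoder$state <- best$state
  }
  model@encoder$stages <- params$encoder
  model@lstm <- params$lstm
  model@head <- params$head
  attr(model, "history") <- hist
  model
})
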