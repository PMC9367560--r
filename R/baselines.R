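# Counterpart methods: volume doubling time (VDT) with two cutoff policies,
# static CNN variants trained on selected time points, and an
# interval-blind CNN+LSTM sequence model.

#' Volume doubling time between two measurements
#'
#' Schwartz exponential form: `VDT = dt * ln(2) / ln(v2 / v1)`. The ranking
#' score is the reciprocal, `1/VDT = ln(v2/v1) / (dt * ln 2)`, which is 0
#' for a static nodule and negative for shrinkage, so every nodule gets a
#' finite score and stable or shrinking nodules order below all growers.
#'
#' @param v1,v2 volumes in mm^3 at the earlier/later scan (> 0).
#' @param dt elapsed days (> 0).
#' @return a [VDTResult-class].
#' @export
#' @examples
#' computeVDT(100, 200, 100)   # doubling in 100 days -> VDT = 100
computeVDT <- function(v1, v2, dt) {
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) {
    stop("volumes must be positive")
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  inv <- log(v2 / v1) / (dt * log(2))
  vdt <- if (inv == 0) Inf else 1 / inv
  new("VDTResult", vdtDays = vdt, invVdt = inv)
}

#' VDT score of a follow-up series
#'
#' Computed between the first and the last scan of the series (the longest,
#' most stable interval, giving one score per nodule).
#'
#' @param series a [FollowUpSeries-class] with at least two time points.
#' @return a [VDTResult-class].
#' @export
vdtScoreSeries <- function(series) {
  n <- nTimepoints(series)
  if (n < 2L) stop("series must have at least two time points")
  v <- volumes(series)
  t <- seriesTimes(series)
  computeVDT(v[1], v[n], t[n] - t[1])
}

#' Classify a VDT result under a cutoff rule
#'
#' Fixed 400-day rule: positive iff `0 < VDT < 400` days (fast growth).
#' Youden rule: positive iff `1/VDT >= threshold`, with the threshold chosen
#' on a validation set by [bestYoudenCutoff()].
#'
#' @param res a [VDTResult-class].
#' @param rule a [CutoffRule-class].
#' @return `"positive"` or `"negative"`.
#' @export
vdtClassify <- function(res, rule) {
  pos <- if (rule@origin == "fixed_400_days") {
    is.finite(res@vdtDays) && res@vdtDays > 0 && res@vdtDays < rule@threshold
  } else if (rule@direction == ">=") {
    res@invVdt >= rule@threshold
  } else {
    res@invVdt <= rule@threshold
  }
  if (pos) "positive" else "negative"
}

#' The fixed 400-day fast-growth rule
#' @return a [CutoffRule-class] with origin `"fixed_400_days"`.
#' @export
vdt400Rule <- function() {
  new("CutoffRule", threshold = 400, direction = ">=",
      origin = "fixed_400_days")
}

# --- static CNN ------------------------------------------------------------

#' Construct a static CNN scorer
#'
#' The shared 3D CNN backbone plus a linear-sigmoid head, scoring a single
#' patch. Which time points it is trained on is set at training time
#' ([trainModel()] with `cfg$trainPolicy` one of `first_only`, `last_only`,
#' `all_points`); the trained model can be queried at any time point.
#'
#' @inheritParams vistaModel
#' @return a [CNNScorer-class].
#' @export
cnnScorer <- function(patchSize = 32L, channels = c(8L, 16L, 32L, 32L),
                      dropout = 0.2, seed = 1L) {
  set.seed(seed)
  enc <- newEncoder(channels, 1L, patchSize)
  D <- enc$dim
  head <- list(w = stats::rnorm(D, sd = sqrt(1 / D)), b = 0)
  new("CNNScorer", encoder = enc, head = head,
      config = list(patchSize = patchSize, channels = channels, dim = D,
                    dropout = dropout, seed = seed, trainPolicy = NULL))
}

#' @describeIn predictIA static CNN: scores one patch of the series;
#'   `at = "last"` (default) or `"first"` selects it. `perStep` holds the
#'   score of every patch evaluated independently.
#' @param at which time point a `CNNScorer` evaluates.
#' @export
setMethod("predictIA", signature("CNNScorer", "FollowUpSeries"),
  function(model, series, at = c("last", "first"), ...) {
    at <- match.arg(at)
    feats <- encodePatches(model, patches(series))
    p <- sigmoidv(drop(feats %*% model@head$w) + model@head$b)
    k <- if (at == "last") length(p) else 1L
    new("IAPrediction", pIA = p[k], perStep = p)
  })

# --- CNN + LSTM ------------------------------------------------------------

newLSTM <- function(dim, hidden) {
  b <- numeric(4L * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias at 1, standard init
  list(
    Wx = xavierMatrix(dim, 4L * hidden),
    Wh = xavierMatrix(hidden, 4L * hidden),
    b = b
  )
}

# x: T x D. Gates in blocks (i, f, o, g). Time stamps are never consumed:
# the model is interval-blind by construction.
lstmForward <- function(p, x) {
  Tn <- nrow(x)
  H <- ncol(p$Wh)
  H <- H / 4L
  hs <- matrix(0, Tn + 1L, H)
  cs <- matrix(0, Tn + 1L, H)
  gates <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- drop(x[t, ] %*% p$Wx + hs[t, ] %*% p$Wh) + p$b
    i <- sigmoidv(z[1:H])
    f <- sigmoidv(z[(H + 1):(2 * H)])
    o <- sigmoidv(z[(2 * H + 1):(3 * H)])
    g <- tanh(z[(3 * H + 1):(4 * H)])
    cs[t + 1L, ] <- f * cs[t, ] + i * g
    hs[t + 1L, ] <- o * tanh(cs[t + 1L, ])
    gates[[t]] <- list(i = i, f = f, o = o, g = g)
  }
  list(h = hs[Tn + 1L, ], cache = list(x = x, hs = hs, cs = cs,
                                       gates = gates, H = H))
}

lstmBackward <- function(p, cache, dh) {
  x <- cache$x
  Tn <- nrow(x)
  H <- cache$H
  dWx <- p$Wx * 0
  dWh <- p$Wh * 0
  db <- p$b * 0
  dx <- x * 0
  dc <- numeric(H)
  for (t in Tn:1) {
    g <- cache$gates[[t]]
    cpost <- cache$cs[t + 1L, ]
    tc <- tanh(cpost)
    do <- dh * tc
    dc <- dc + dh * g$o * (1 - tc^2)
    di <- dc * g$g
    dg <- dc * g$i
    df <- dc * cache$cs[t, ]
    dcprev <- dc * g$f
    dz <- c(di * g$i * (1 - g$i),
            df * g$f * (1 - g$f),
            do * g$o * (1 - g$o),
            dg * (1 - g$g^2))
    dWx <- dWx + outer(x[t, ], dz)
    dWh <- dWh + outer(cache$hs[t, ], dz)
    db <- db + dz
    dx[t, ] <- dz %*% t(p$Wx)
    dh <- drop(dz %*% t(p$Wh))
    dc <- dcprev
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

#' Construct a CNN+LSTM baseline
#'
#' The shared CNN backbone feeds per-time-point encodings, in scan order, to
#' a single-layer LSTM; the final hidden state passes through a
#' linear-sigmoid head. Scan times are never consumed, so the model treats
#' all series as if they were regularly sampled.
#'
#' @inheritParams vistaModel
#' @param hidden LSTM hidden dimension (default: the feature dimension D).
#' @return a [CNNLSTMModel-class].
#' @export
cnnLstmModel <- function(patchSize = 32L, channels = c(8L, 16L, 32L, 32L),
                         hidden = NULL, dropout = 0.2, seed = 1L) {
  set.seed(seed)
  enc <- newEncoder(channels, 1L, patchSize)
  D <- enc$dim
  if (is.null(hidden)) hidden <- D
  lstm <- newLSTM(D, hidden)
  head <- list(w = stats::rnorm(hidden, sd = sqrt(1 / hidden)), b = 0)
  new("CNNLSTMModel", encoder = enc, lstm = lstm, head = head,
      config = list(patchSize = patchSize, channels = channels, dim = D,
                    hidden = hidden, dropout = dropout, seed = seed))
}

#' @describeIn predictIA CNN+LSTM: encodes every patch, runs the recurrence
#'   in scan order, and reads the head at the final hidden state. `perStep`
#'   holds the head output after each prefix.
#' @export
setMethod("predictIA", signature("CNNLSTMModel", "FollowUpSeries"),
  function(model, series, ...) {
    feats <- encodePatches(model, patches(series))
    fwd <- lstmForward(model@lstm, feats)
    hs <- fwd$cache$hs[-1L, , drop = FALSE]
    p <- sigmoidv(drop(hs %*% model@head$w) + model@head$b)
    new("IAPrediction", pIA = p[length(p)], perStep = p)
  })
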