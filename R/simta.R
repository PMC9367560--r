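# SimTA: causal temporal attention for asynchronous follow-up series.
#
# For a series scanned at days t_1 < ... < t_T, the attention paid by step j
# to step i <= j is a softmax over scores
#     s[j, i] = -rate * (t_j - t_i) / timeScale,
# so weights decay exponentially with elapsed time and the most recent scans
# always receive the largest weight. The decay rate is a learnable per-layer
# scalar, kept non-negative through a softplus reparametrization. No
# query/key content terms enter the scores: attention is driven by time
# alone, which is what makes the module usable on arbitrarily irregular
# sampling.

#' SimTA attention weights for a scan schedule
#'
#' Builds the causal attention matrix for one follow-up schedule. Row `j`
#' holds the weights with which time point `j` attends to time points
#' `1..j`: a softmax over `-rate * (t_j - t_i) / timeScale`. Entries above
#' the diagonal are structurally zero.
#'
#' @param times numeric vector of scan times in days, strictly increasing.
#' @param rate non-negative decay rate per `timeScale` days. `rate = 0`
#'   gives uniform weights over the prefix; large rates concentrate all
#'   weight on the current scan.
#' @param timeScale days per attention time unit (default 30).
#' @return a `T x T` lower-triangular matrix; each row sums to 1 and within
#'   a row weights are non-decreasing toward the present.
#' @export
#' @examples
#' simtaAttention(c(0, 30, 60), rate = 3)   # row 3: softmax(-6, -3, 0)
simtaAttention <- function(times, rate, timeScale = 30) {
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (rate < 0) stop("rate must be non-negative")
  Tn <- length(times)
  A <- matrix(0, Tn, Tn)
  for (j in seq_len(Tn)) {
    s <- -rate * (times[j] - times[seq_len(j)]) / timeScale
    s <- s - max(s)
    e <- exp(s)
    A[j, seq_len(j)] <- e / sum(e)
  }
  A
}

newSimtaLayer <- function(dim, ffnMult = 1L, rateInit = 0.5) {
  dff <- dim * ffnMult
  list(
    # softplus(lam) == rateInit; for large rates softplus is the identity
    lam = if (rateInit > 30) rateInit else log(expm1(rateInit)),
    # residual branches start small (near-identity layer), which keeps the
    # post-LN stack in a well-conditioned regime early in training
    Wv = 0.1 * xavierMatrix(dim, dim), bv = numeric(dim),
    g1 = rep(1, dim), b1 = numeric(dim),
    W1 = heMatrix(dim, dff), bf1 = numeric(dff),
    W2 = 0.1 * xavierMatrix(dff, dim), bf2 = numeric(dim),
    g2 = rep(1, dim), b2 = numeric(dim)
  )
}

# Forward through one SimTA layer. x: T x D features of one series.
simtaLayerForward <- function(p, x, times, timeScale, dropout = 0,
                              train = FALSE) {
  rate <- softplus(p$lam)
  A <- simtaAttention(times, rate, timeScale)
  Vx <- denseForward(x, p$Wv, p$bv)
  ctx <- A %*% Vx
  m1 <- if (train && dropout > 0) dropoutMask(ctx, dropout) else NULL
  u1 <- x + applyMask(ctx, m1)
  ln1 <- layernormForward(u1, p$g1, p$b1)
  h1 <- ln1$y
  z <- denseForward(h1, p$W1, p$bf1)
  zr <- pmax(z, 0)
  f <- denseForward(zr, p$W2, p$bf2)
  m2 <- if (train && dropout > 0) dropoutMask(f, dropout) else NULL
  u2 <- h1 + applyMask(f, m2)
  ln2 <- layernormForward(u2, p$g2, p$b2)
  list(y = ln2$y,
       cache = list(x = x, times = times, A = A, Vx = Vx, rate = rate,
                    m1 = m1, h1 = h1, z = z, zr = zr, m2 = m2,
                    ln1 = ln1$cache, ln2 = ln2$cache,
                    timeScale = timeScale))
}

simtaLayerBackward <- function(p, cache, dy) {
  lnb2 <- layernormBackward(cache$ln2, dy)
  du2 <- lnb2$dx
  df <- applyMask(du2, cache$m2)
  d2 <- denseBackward(cache$zr, p$W2, df)
  dzr <- d2$dx * (cache$z > 0)
  d1 <- denseBackward(cache$h1, p$W1, dzr)
  dh1 <- du2 + d1$dx
  lnb1 <- layernormBackward(cache$ln1, dh1)
  du1 <- lnb1$dx
  dctx <- applyMask(du1, cache$m1)
  # ctx = A Vx
  dA <- dctx %*% t(cache$Vx)
  dVx <- t(cache$A) %*% dctx
  dv <- denseBackward(cache$x, p$Wv, dVx)
  dx <- du1 + dv$dx
  # rate gradient through the causal softmax rows
  times <- cache$times
  A <- cache$A
  drate <- 0
  for (j in seq_along(times)) {
    idx <- seq_len(j)
    a <- A[j, idx]
    g <- dA[j, idx]
    ds <- a * (g - sum(a * g))
    dsdr <- -(times[j] - times[idx]) / cache$timeScale
    drate <- drate + sum(ds * dsdr)
  }
  dlam <- drate * sigmoidv(p$lam)   # d softplus
  grads <- list(lam = dlam,
                Wv = dv$dW, bv = dv$db,
                g1 = lnb1$dg, b1 = lnb1$db,
                W1 = d1$dW, bf1 = d1$db,
                W2 = d2$dW, bf2 = d2$db,
                g2 = lnb2$dg, b2 = lnb2$db)
  list(dx = dx, grads = grads)
}

#' Construct a ViSTA model
#'
#' A per-time-point 3D CNN encoder, a stack of SimTA layers over the encoded
#' sequence, and a linear-sigmoid head applied to every step's representation.
#' The prediction for a series is the head output at its final step; the
#' per-step outputs are the predictions the model would have issued at each
#' earlier examination.
#'
#' @param patchSize cubic patch edge in voxels (default 32).
#' @param channels encoder stage widths; the last entry is the feature
#'   dimension D.
#' @param nLayers number of SimTA layers.
#' @param timeScale days per attention time unit.
#' @param dropout dropout probability used during training.
#' @param ffnMult width multiplier of the per-step feed-forward block.
#' @param rateInit initial decay rate(s) after softplus, recycled over
#'   layers. The default staggers the layers across time scales (a slow,
#'   long-memory layer and a fast, recency-driven layer), so the stack sees
#'   differently discounted views of the history from the start — the
#'   contrast between them is what encodes a growth rate.
#' @param seed integer seed for weight initialization.
#' @return a [VistaModel-class].
#' @export
vistaModel <- function(patchSize = 32L, channels = c(8L, 16L, 32L, 32L),
                       nLayers = 2L, timeScale = 30, dropout = 0.2,
                       ffnMult = 1L, rateInit = c(0.1, 1), seed = 1L) {
  set.seed(seed)
  enc <- newEncoder(channels, 1L, patchSize)
  D <- enc$dim
  rates <- rep_len(rateInit, nLayers)
  simta <- lapply(seq_len(nLayers), function(i) newSimtaLayer(D, ffnMult,
                                                              rates[i]))
  names(simta) <- paste0("l", seq_len(nLayers))
  head <- list(w = stats::rnorm(D, sd = sqrt(1 / D)), b = 0)
  new("VistaModel", encoder = enc, simta = simta, head = head,
      config = list(patchSize = patchSize, channels = channels, dim = D,
                    nLayers = nLayers, timeScale = timeScale,
                    dropout = dropout, ffnMult = ffnMult, seed = seed))
}

# Forward over encoded features of one series. feats: T x D.
vistaSequenceForward <- function(model, feats, times, train = FALSE) {
  caches <- vector("list", length(model@simta))
  h <- feats
  for (i in seq_along(model@simta)) {
    out <- simtaLayerForward(model@simta[[i]], h, times,
                             model@config$timeScale,
                             model@config$dropout, train)
    caches[[i]] <- out$cache
    h <- out$y
  }
  logits <- drop(h %*% model@head$w) + model@head$b
  list(perStep = sigmoidv(logits), logits = logits, h = h, caches = caches)
}

# Backward from d(logit at each step) to features and parameter gradients.
vistaSequenceBackward <- function(model, fwd, dlogits) {
  dh <- outer(dlogits, model@head$w)
  dw <- colSums(fwd$h * dlogits)
  db <- sum(dlogits)
  grads <- vector("list", length(model@simta))
  names(grads) <- names(model@simta)
  for (i in rev(seq_along(model@simta))) {
    bk <- simtaLayerBackward(model@simta[[i]], fwd$caches[[i]], dh)
    grads[[i]] <- bk$grads
    dh <- bk$dx
  }
  list(dfeat = dh, simta = grads, head = list(w = dw, b = db))
}

#' @describeIn predictIA ViSTA: encode each patch, run the SimTA stack, and
#'   read the sigmoid head at every prefix; `pIA` is the final step's value.
#' @export
setMethod("predictIA", signature("VistaModel", "FollowUpSeries"),
  function(model, series, ...) {
    if (nTimepoints(series) < 1L) stop("empty series")
    x <- patchArray(patches(series))
    ef <- encoderForward(model@encoder, x, train = FALSE)
    fwd <- vistaSequenceForward(model, ef$feat, seriesTimes(series),
                                train = FALSE)
    new("IAPrediction", pIA = fwd$perStep[length(fwd$perStep)],
        perStep = fwd$perStep)
  })

#' Encode patches into feature vectors
#'
#' Runs the CNN backbone of a model in inference mode on a batch of patches.
#'
#' @param model a [VistaModel-class], [CNNScorer-class] or
#'   [CNNLSTMModel-class].
#' @param plist list of 3D patch arrays (or a single array).
#' @return numeric matrix, one row of D features per patch.
#' @export
encodePatches <- function(model, plist) {
  if (!is.list(plist)) plist <- list(plist)
  x <- patchArray(plist)
  encoderForward(model@encoder, x, train = FALSE)$feat
}

# stack a list of (s,s,s) arrays into (s,s,s,1,N)
patchArray <- function(plist) {
  s <- dim(plist[[1]])
  x <- array(unlist(plist, use.names = FALSE), dim = c(s, 1L, length(plist)))
  x
}

# flatten a patch list into an (s^3 x N) matrix for fast column subsetting
patchMatrix <- function(plist) {
  s <- dim(plist[[1]])[1]
  matrix(unlist(plist, use.names = FALSE), nrow = s^3)
}

# columns sel of a patch matrix as an encoder input array
batchFromMatrix <- function(m, patchSize, sel) {
  x <- m[, sel, drop = FALSE]
  dim(x) <- c(patchSize, patchSize, patchSize, 1L, length(sel))
  x
}

.countTree <- function(...) sum(vapply(list(...), treeScalarCount, 0))

#' @rdname countParams
#' @export
setMethod("countParams", "VistaModel", function(model, includeBackbone = TRUE) {
  n <- .countTree(model@simta, model@head)
  if (includeBackbone) n <- n + treeScalarCount(model@encoder$stages)
  as.integer(n)
})

#' @rdname countParams
#' @export
setMethod("countParams", "CNNScorer", function(model, includeBackbone = TRUE) {
  n <- .countTree(model@head)
  if (includeBackbone) n <- n + treeScalarCount(model@encoder$stages)
  as.integer(n)
})

#' @rdname countParams
#' @export
setMethod("countParams", "CNNLSTMModel", function(model,
                                                  includeBackbone = TRUE) {
  n <- .countTree(model@lstm, model@head)
  if (includeBackbone) n <- n + treeScalarCount(model@encoder$stages)
  as.integer(n)
})
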