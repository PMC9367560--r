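# Minimal neural-network engine used by the encoder, the SimTA layers and the
# recurrent baseline. Everything operates on plain numeric arrays; gradients
# are computed by explicit backward functions (verified against central
# differences in the test suite). The only compiled pieces are the 3D
# convolution forward/backward in src/.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoidv <- function(x) 1 / (1 + exp(-x))

#' Cosine-decay learning-rate schedule
#'
#' `lr(e) = lrMin + 0.5 (lrMax - lrMin) (1 + cos(pi e / epochs))` with
#' zero-based epoch index `e`, so the first update uses `lrMax` and the rate
#' approaches `lrMin` as `e` reaches `epochs`.
#'
#' @param epoch zero-based epoch index.
#' @param epochs total number of epochs.
#' @param lrMax,lrMin schedule endpoints.
#' @return numeric learning rate.
#' @export
#' @examples
#' cosineLR(0, 100)        # 1e-3
#' cosineLR(50, 100)       # midpoint, ~5.005e-4
cosineLR <- function(epoch, epochs, lrMax = 1e-3, lrMin = 1e-6) {
  stopifnot(lrMin <= lrMax, epochs >= 1)
  lrMin + 0.5 * (lrMax - lrMin) * (1 + cos(pi * epoch / epochs))
}

# --- parameter trees -------------------------------------------------------
# Parameters live in nested named lists of numeric arrays. mapTree applies a
# function leaf-wise over parallel trees; flattenTree counts scalars.

mapTree <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(mapTree, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

treeScalarCount <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, treeScalarCount, 0)) else length(tree)
}

zeroLike <- function(tree) mapTree(function(p) p * 0, tree)

addTrees <- function(a, b) mapTree(`+`, a, b)

treeSumSq <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, treeSumSq, 0)) else sum(tree^2)
}

# global L2 gradient-norm clipping
clipTree <- function(grads, maxNorm) {
  if (is.null(maxNorm) || !is.finite(maxNorm)) return(grads)
  nrm <- sqrt(treeSumSq(grads))
  if (nrm <= maxNorm) grads else mapTree(function(g) g * (maxNorm / nrm),
                                         grads)
}

# --- AdamW -----------------------------------------------------------------
# Decoupled weight decay is applied to weight matrices/arrays only (rank >= 2),
# not to biases, normalization gains or the attention decay scalar, following
# common practice.

adamwInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamwStep <- function(params, grads, state, lr, weightDecay = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- mapTree(function(m, g) beta1 * m + (1 - beta1) * g,
                     state$m, grads)
  state$v <- mapTree(function(v, g) beta2 * v + (1 - beta2) * g * g,
                     state$v, grads)
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  params <- mapTree(function(p, m, v) {
    upd <- (m / c1) / (sqrt(v / c2) + eps)
    wd <- if (!is.null(dim(p)) && length(dim(p)) >= 2L) weightDecay * p else 0
    p - lr * (upd + wd)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# --- elementary layers -----------------------------------------------------

denseForward <- function(x, W, b) {
  # x: n x din matrix
  sweep(x %*% W, 2, b, `+`)
}

denseBackward <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

layernormForward <- function(x, g, b, eps = 1e-5) {
  # row-wise normalization over the feature dimension
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernormBackward <- function(cache, dy) {
  xhat <- cache$xhat
  inv <- cache$inv
  d <- ncol(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$g, `*`)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

dropoutMask <- function(dimlike, p) {
  if (p <= 0) return(NULL)
  m <- (stats::runif(length(dimlike)) >= p) / (1 - p)
  array(m, dim = dim(dimlike) %||% length(dimlike))
}

applyMask <- function(x, m) if (is.null(m)) x else x * m

# --- initializers ----------------------------------------------------------

heMatrix <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
}

xavierMatrix <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(1 / din)), din, dout)
}
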