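# Patch encoder: a small 3D convolutional network. Each stage is a 3x3x3
# convolution with stride 2 (halving each spatial axis), batch normalization
# and ReLU; global average pooling over the remaining grid yields a learned
# feature vector per patch, to which two fixed first-order intensity
# statistics are appended: log occupancy above the ground-glass and the
# solid attenuation level. These are the canonical size/composition
# measurements of nodule follow-up; carrying them alongside the learned
# features guarantees that cross-scan size contrast survives encoding, which
# is what the downstream temporal models integrate. The stage pipeline runs
# in compiled code (src/encoder.cpp); this file holds the parameter
# container and thin wrappers. Default widths 8-16-32-32 are sized for
# single-CPU training.

# normalized-intensity thresholds: ~ -580 HU (ground glass) and -160 HU
# (solid) on the [0,1] scale of clipNormalize()
.encStatThresholds <- c(0.30, 0.60)

.encStats <- function(x) {
  # x: (s,s,s,1,N) array -> N x 2 matrix of log-occupancies
  dm <- dim(x)
  nvox <- prod(dm[1:4])
  m <- matrix(x, nrow = nvox)
  # affine-standardized so the statistics live on the same O(1) scale as the
  # learned features (log occupancy spans roughly -9..-1 on a 32^3 grid)
  out <- vapply(.encStatThresholds,
                function(th) (log(colMeans(m > th) + 1e-4) + 5) / 2,
                numeric(dm[5]))
  matrix(out, nrow = dm[5])
}

newEncoder <- function(channels = c(8L, 16L, 32L, 32L), inChannels = 1L,
                       patchSize = 32L) {
  nStages <- length(channels)
  if (patchSize %% (2^nStages) != 0) {
    stop("patchSize must be divisible by 2^nStages")
  }
  cins <- c(inChannels, channels[-nStages])
  stages <- vector("list", nStages)
  names(stages) <- paste0("s", seq_len(nStages))
  state <- vector("list", nStages)
  for (i in seq_len(nStages)) {
    K <- 27L * cins[i]
    stages[[i]] <- list(
      W = heMatrix(K, channels[i]),
      b = numeric(channels[i]),
      gamma = rep(1, channels[i]),
      beta = numeric(channels[i])
    )
    state[[i]] <- list(rm = numeric(channels[i]), rv = rep(1, channels[i]))
  }
  list(stages = stages, state = state, channels = channels,
       inChannels = inChannels, patchSize = patchSize,
       dim = channels[nStages] + length(.encStatThresholds))
}

# x: array (s,s,s,N) or (s,s,s,Cin,N). Returns N x D features and a cache.
encoderForward <- function(enc, x, train = FALSE) {
  dm <- dim(x)
  if (length(dm) == 4L) dim(x) <- c(dm[1:3], 1L, dm[4])
  res <- .encForward(x, dim(x), enc$stages, enc$state, train, 0.1, 1e-5)
  list(feat = cbind(res$feat, .encStats(x)),
       caches = list(x = x, fwd = res, train = train),
       state = res$state)
}

# dfeat: N x D. Returns per-stage gradients and optionally d(input). The
# appended occupancy statistics are step functions of the voxels, so their
# input gradient is zero almost everywhere and they contribute none.
encoderBackward <- function(enc, caches, dfeat, needDx = FALSE) {
  nLearned <- ncol(dfeat) - length(.encStatThresholds)
  dfeat <- dfeat[, seq_len(nLearned), drop = FALSE]
  res <- .encBackward(caches$x, dim(caches$x), enc$stages, caches$fwd,
                      dfeat, caches$train, needDx)
  grads <- res$grads
  names(grads) <- names(enc$stages)
  list(grads = grads, dx = if (needDx) res$dx else NULL)
}
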