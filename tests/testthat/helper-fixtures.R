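# Shared fixtures: everything is generated in code at test time.

# a follow-up series with random patches (no rendering), for model-level tests
makePatchSeries <- function(Tn, patchSize = 8L, seed = 1L,
                            times = NULL, label = "IA") {
  set.seed(seed)
  if (is.null(times)) times <- c(0, cumsum(round(30 + runif(Tn - 1, 0, 200))))
  new("FollowUpSeries", seriesId = sprintf("T%02d", seed), times = times,
      patches = lapply(seq_len(Tn), function(i) {
        array(runif(patchSize^3), rep(patchSize, 3))
      }),
      volumes = rep(100, Tn), label = label)
}

# tiny ViSTA for gradient and behavioral tests (8^3 patches, 2-stage encoder)
tinyVista <- function(seed = 3L, nLayers = 2L, dropout = 0,
                      rateInit = 0.5) {
  vistaModel(patchSize = 8L, channels = c(3L, 4L), nLayers = nLayers,
             dropout = dropout, rateInit = rateInit, seed = seed)
}

# small in-memory labelled dataset for training smoke tests
tinyDataset <- function(n = 16L, seed = 7L, patchSize = 16L) {
  ds <- generateDataset(nSeries = n, seed = seed, patchSize = patchSize,
                        split = c(train = 0.5, val = 0.25, test = 0.25))
  splitDataset(ds)
}

# noise-free exponentially growing series with controlled parameters
cleanGrowthSeries <- function(dtDouble, v0 = sphereVol(4), solid = 0.3,
                              seed = 5L, seriesId = "G1") {
  set.seed(seed)
  p <- new("GrowthParams", modelKind = "exponential", v0 = v0,
           dtDouble = dtDouble, solid0 = solid, solidEnd = solid,
           noiseSd = 0, backgroundHu = -850)
  sampleSeries(p, seriesId = seriesId)
}

sphereVol <- function(r) 4 / 3 * pi * r^3

# independent finite-difference gradient of f at x[idx]
numGrad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}
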