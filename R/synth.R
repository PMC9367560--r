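# Synthetic follow-up generator. Emulates the study conditions that the real
# (private) cohort exhibits: 2-11 scans per nodule, first-to-last spans of
# 30-2813 days with median near one year, ground-glass nodules on lung
# background that grow (exponentially by default) and may develop a solid
# core, and a nodule-level train/validation/test split. The invasiveness
# label is tied to the growth parameters: fast doubling or solid
# transformation marks a nodule as IA, with a small label-noise rate so the
# classification task is not separable.

sphereVolume <- function(r) 4 / 3 * pi * r^3
sphereRadius <- function(v) (3 * v / (4 * pi))^(1 / 3)

#' Defaults of the synthetic nodule generator
#'
#' Returns the configuration list all sampling functions draw from. IA
#' nodules receive stochastically shorter doubling times (log-normal, median
#' 150 days, mostly below the 400-day fast-growth convention) and larger
#' final solid fractions than non-IA nodules (median doubling time 800 days,
#' 30% of them static). Inter-scan gaps are log-normal
#' (`30 + round(rlnorm(log(25), 1.1))` days, capped at 900), which puts the
#' median first-to-last span near one year.
#'
#' @return named list of generator defaults.
#' @export
synthConfig <- function() {
  list(
    # growth, by class: doubling-time distributions straddle the 400-day
    # fast-growth convention so that accurate rate estimation matters
    iaDtMeanlog = log(180), iaDtSdlog = 0.5,
    nonIaDtMeanlog = log(750), nonIaDtSdlog = 0.5,
    nonIaStaticProb = 0.25,
    iaSolidShape = c(2.2, 2.2), nonIaSolidShape = c(1.2, 3),
    solid0Shape = c(1, 3),
    r0Range = c(2.5, 7),            # initial radius, mm
    maxRadius = 13,                 # hard rendering cap (grid capacity), mm
    resectRadius = 10,              # follow-up stops once the nodule passes this
    # schedule: series length 2 + truncated geometric (mean ~3.5 scans, as in
    # the emulated cohort's 1234 scans over 351 nodules, max 11); a
    # per-series follow-up tempo scales the inter-scan gaps, so scan count
    # alone does not determine elapsed time
    lenGeomP = 0.40, lenRange = c(2L, 11L),
    gapMeanlog = log(130), gapSdlog = 0.9, tempoSdlog = 0.5,
    gapMin = 30, gapMax = 900, spanMax = 2813,
    # imaging
    backgroundHu = -850, shellHu = -600, coreHu = 0, noiseSd = 30,
    huClip = c(-1024, 400),
    # labelling
    fastGrowthDays = 400, solidLabelCut = 0.5, labelNoise = 0.05
  )
}

#' Draw growth parameters for one synthetic nodule
#'
#' Uses the current R random-number stream; seed it with [set.seed()] for
#' reproducibility. IA draws have stochastically shorter doubling times and
#' larger final solid fractions than non-IA draws (see [synthConfig()]).
#'
#' @param classLabel `"IA"` or `"non-IA"`.
#' @param cfg generator configuration, see [synthConfig()].
#' @return a [GrowthParams-class].
#' @export
sampleGrowthParams <- function(classLabel = c("IA", "non-IA"),
                               cfg = synthConfig()) {
  classLabel <- match.arg(classLabel)
  if (classLabel == "IA") {
    dt <- max(30, stats::rlnorm(1, cfg$iaDtMeanlog, cfg$iaDtSdlog))
    se <- stats::rbeta(1, cfg$iaSolidShape[1], cfg$iaSolidShape[2])
  } else {
    dt <- if (stats::runif(1) < cfg$nonIaStaticProb) Inf else
      max(30, stats::rlnorm(1, cfg$nonIaDtMeanlog, cfg$nonIaDtSdlog))
    se <- stats::rbeta(1, cfg$nonIaSolidShape[1], cfg$nonIaSolidShape[2])
  }
  s0 <- se * stats::rbeta(1, cfg$solid0Shape[1], cfg$solid0Shape[2])
  v0 <- sphereVolume(stats::runif(1, cfg$r0Range[1], cfg$r0Range[2]))
  new("GrowthParams", modelKind = "exponential", v0 = v0, dtDouble = dt,
      solid0 = s0, solidEnd = se, noiseSd = cfg$noiseSd,
      backgroundHu = cfg$backgroundHu)
}

#' Nodule volume under a growth law
#'
#' Exponential: `v(t) = v0 * 2^(t / dtDouble)`. Gompertz: saturating growth
#' toward `vmax` whose initial relative growth rate matches the exponential
#' law. Both are capped at `vmax`, the largest sphere the image grid can
#' hold.
#'
#' @param params a [GrowthParams-class].
#' @param t days since the first scan (vectorized).
#' @param vmax saturation volume in mm^3 (default: sphere of the
#'   [synthConfig()] `maxRadius`).
#' @return numeric volumes, mm^3.
#' @export
growthVolume <- function(params, t, vmax = sphereVolume(synthConfig()$maxRadius)) {
  if (!is.finite(params@dtDouble)) return(rep(params@v0, length(t)))
  v <- if (params@modelKind == "exponential") {
    params@v0 * 2^(t / params@dtDouble)
  } else {
    K <- vmax
    alpha <- log(2) / (params@dtDouble * log(K / params@v0))
    K * (params@v0 / K)^(exp(-alpha * t))
  }
  pmin(v, vmax)
}

labelRule <- function(params, cfg = synthConfig()) {
  ia <- (is.finite(params@dtDouble) && params@dtDouble < cfg$fastGrowthDays) ||
    params@solidEnd > cfg$solidLabelCut
  if (ia) "IA" else "non-IA"
}

#' Render a nodule phantom into an HU image grid
#'
#' Voxelizes a sphere of the requested volume at the grid center: a
#' ground-glass shell with a concentric solid core occupying
#' `solidFraction` of the nodule volume, on lung-parenchyma background, with
#' optional additive Gaussian noise. HU values are clipped to
#' \[-1024, 400\].
#'
#' @param volumeMm3 nodule volume, mm^3 (> 0).
#' @param solidFraction solid-core volume fraction in \[0, 1\].
#' @param gridShape integer(3) voxel counts.
#' @param spacing numeric(3) mm per voxel.
#' @param noiseSd additive noise SD in HU.
#' @param cfg attenuation constants, see [synthConfig()].
#' @return list with `image` and `mask`, both [CTVolume-class].
#' @export
renderNodule <- function(volumeMm3, solidFraction, gridShape = c(48L, 48L, 48L),
                         spacing = c(1, 1, 1), noiseSd = 0,
                         cfg = synthConfig()) {
  stopifnot(volumeMm3 > 0, solidFraction >= 0, solidFraction <= 1)
  r <- sphereRadius(volumeMm3)
  extent <- gridShape * spacing
  if (2 * r > min(extent)) stop("nodule exceeds patch")
  ctr <- (gridShape + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(gridShape[a]) - ctr[a]) * spacing[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask <- d2 <= r^2
  rc <- r * solidFraction^(1 / 3)
  img <- array(cfg$backgroundHu, dim = gridShape)
  img[mask] <- cfg$shellHu
  img[d2 <= rc^2] <- cfg$coreHu
  if (noiseSd > 0) img <- img + stats::rnorm(length(img), sd = noiseSd)
  img <- pmin(pmax(img, cfg$huClip[1]), cfg$huClip[2])
  dim(img) <- gridShape
  storage.mode(mask) <- "double"
  list(image = new("CTVolume", voxels = img, spacing = spacing),
       mask = new("CTVolume", voxels = array(mask, gridShape),
                  spacing = spacing))
}

#' Draw a follow-up scan schedule
#'
#' Number of scans is 2 plus a truncated geometric (mean about 3.5, maximum
#' 11, matching the emulated cohort's scan-per-nodule ratio); inter-scan
#' gaps are right-skewed on \[30, 900\] days, scaled by a per-series
#' follow-up tempo; schedules whose total span exceeds 2813 days are
#' redrawn. The resulting first-to-last span has median near one year.
#' Uses the current RNG stream.
#'
#' @param cfg generator configuration.
#' @return numeric vector of days since the first scan, starting at 0.
#' @export
sampleSchedule <- function(cfg = synthConfig()) {
  L <- cfg$lenRange[1] + min(stats::rgeom(1, cfg$lenGeomP),
                             cfg$lenRange[2] - cfg$lenRange[1])
  repeat {
    tempo <- stats::rlnorm(1, 0, cfg$tempoSdlog)
    gaps <- pmin(cfg$gapMin + round(tempo * stats::rlnorm(L - 1,
                                                          cfg$gapMeanlog,
                                                          cfg$gapSdlog)),
                 cfg$gapMax)
    if (sum(gaps) <= cfg$spanMax) break
  }
  c(0, cumsum(gaps))
}

#' Sample one synthetic follow-up series
#'
#' Draws a schedule, evolves the nodule volume and solid fraction along it
#' (solid fraction interpolates linearly in time from `solid0` to
#' `solidEnd`), renders every time point, and assigns the invasiveness label
#' from the growth parameters (IA iff doubling time < 400 days or final
#' solid fraction > 0.5), flipped with the configured label-noise
#' probability.
#'
#' @param params a [GrowthParams-class].
#' @param seriesId identifier stored in the result.
#' @param gridShape,spacing rendering grid (defaults: 32^3 voxels at 1 mm,
#'   i.e. directly at the model patch geometry).
#' @param normalize if `TRUE` patches are HU-clipped and min-max normalized
#'   to \[0, 1\] ([clipNormalize()]); otherwise raw HU grids are stored.
#' @param keepRaw keep raw HU images and masks in the result (memory-heavy
#'   for large datasets).
#' @param cfg generator configuration.
#' @return a [FollowUpSeries-class]; mask-derived volumes in `volumes()`,
#'   analytic ground-truth volumes in attribute `"analyticVolumes"`, the
#'   growth parameters in attribute `"params"`. With `keepRaw = TRUE` the HU
#'   images and masks are attached as attributes `"images"` and `"masks"`.
#' @export
sampleSeries <- function(params, seriesId = "S1",
                         gridShape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                         normalize = TRUE, keepRaw = FALSE,
                         cfg = synthConfig()) {
  times <- sampleSchedule(cfg)
  # growth saturates at the largest sphere the rendering grid can hold
  vfit <- sphereVolume(min(gridShape * spacing) / 2 - 1)
  vmax <- min(sphereVolume(cfg$maxRadius), vfit)
  vols <- growthVolume(params, times, vmax)
  # surveillance stops at the first scan where the nodule passes the
  # resection trigger: fast growers end up with short follow-up series
  over <- which(vols > min(sphereVolume(cfg$resectRadius), 0.8 * vmax))
  if (length(over) > 0) {
    keep <- max(2L, over[1])
    times <- times[seq_len(keep)]
    vols <- vols[seq_len(keep)]
  }
  span <- max(times)
  sf <- if (span > 0) {
    params@solid0 + (params@solidEnd - params@solid0) * times / span
  } else {
    rep(params@solidEnd, length(times))
  }
  label <- labelRule(params, cfg)
  if (stats::runif(1) < cfg$labelNoise) {
    label <- if (label == "IA") "non-IA" else "IA"
  }
  pat <- vector("list", length(times))
  mvol <- numeric(length(times))
  imgs <- if (keepRaw) vector("list", length(times)) else NULL
  msks <- if (keepRaw) vector("list", length(times)) else NULL
  for (i in seq_along(times)) {
    rn <- renderNodule(vols[i], sf[i], gridShape, spacing, params@noiseSd, cfg)
    mvol[i] <- sum(rn$mask@voxels) * prod(spacing)
    pat[[i]] <- if (normalize) clipNormalize(rn$image)@voxels else
      rn$image@voxels
    if (keepRaw) {
      imgs[[i]] <- rn$image
      msks[[i]] <- rn$mask
    }
  }
  out <- new("FollowUpSeries", seriesId = seriesId, times = times,
             patches = pat, volumes = mvol, label = label)
  attr(out, "analyticVolumes") <- vols
  attr(out, "params") <- params
  if (keepRaw) {
    attr(out, "images") <- imgs
    attr(out, "masks") <- msks
  }
  out
}

# nodule-level split with exact counts; remainders go to the largest
# fractional parts so that e.g. 351 * (245, 37, 69)/351 is hit exactly.
splitCounts <- function(n, fractions) {
  raw <- n * fractions
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a full synthetic dataset
#'
#' Samples `nSeries` follow-up series with ground-truth labels and a
#' nodule-level train/validation/test split (every scan of a series shares
#' its split). With `dir` given, writes one NIfTI image and mask per scan
#' plus a CSV manifest (`series_id,timepoint,days,image,mask,volume_mm3,
#' label,split`); rendering then uses `gridShape`/`spacing` (default 48^3 at
#' 1 mm). Without `dir`, series are kept in memory with normalized patches
#' at the model geometry (`patchSize`^3 at 1 mm) and the manifest's path
#' columns are empty.
#'
#' @param nSeries number of nodules (default 351).
#' @param iaFraction fraction of IA nodules (default 160/351).
#' @param split named fractions summing to 1 (default 245/37/69 of 351).
#' @param seed integer seed; all output is a pure function of the
#'   configuration and this seed.
#' @param dir output directory for NIfTI volumes, or `NULL` for in-memory.
#' @param gridShape,spacing rendering geometry for on-disk volumes.
#' @param patchSize in-memory patch edge (voxels at 1 mm).
#' @param cfg generator configuration.
#' @return list with `series` (list of [FollowUpSeries-class], in-memory
#'   mode only), `manifest` (data.frame), and `split` (named character
#'   vector by series id).
#' @export
generateDataset <- function(nSeries = 351L, iaFraction = 160 / 351,
                            split = c(train = 245, val = 37, test = 69) / 351,
                            seed = 42L, dir = NULL,
                            gridShape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                            patchSize = 32L, cfg = synthConfig()) {
  stopifnot(abs(sum(split) - 1) < 1e-8)
  set.seed(seed)
  writeOut <- !is.null(dir)
  if (writeOut && !dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir)
  }
  nIa <- round(nSeries * iaFraction)
  classes <- sample(c(rep("IA", nIa), rep("non-IA", nSeries - nIa)))
  cnt <- splitCounts(nSeries, split)
  splits <- sample(rep(names(split), cnt))
  ids <- sprintf("S%04d", seq_len(nSeries))
  names(splits) <- ids

  seriesList <- if (writeOut) NULL else vector("list", nSeries)
  rows <- vector("list", nSeries)
  for (s in seq_len(nSeries)) {
    params <- sampleGrowthParams(classes[s], cfg)
    gs <- if (writeOut) gridShape else rep(as.integer(patchSize), 3L)
    sp <- if (writeOut) spacing else c(1, 1, 1)
    ser <- sampleSeries(params, ids[s], gs, sp, normalize = !writeOut,
                        keepRaw = writeOut, cfg = cfg)
    av <- attr(ser, "analyticVolumes")
    nt <- nTimepoints(ser)
    ipath <- mpath <- rep(NA_character_, nt)
    if (writeOut) {
      imgs <- attr(ser, "images")
      msks <- attr(ser, "masks")
      for (k in seq_len(nt)) {
        ipath[k] <- sprintf("%s_t%02d_image.nii.gz", ids[s], k)
        mpath[k] <- sprintf("%s_t%02d_mask.nii.gz", ids[s], k)
        writeCTVolume(imgs[[k]], file.path(dir, ipath[k]))
        writeCTVolume(msks[[k]], file.path(dir, mpath[k]))
      }
    } else {
      seriesList[[s]] <- ser
    }
    rows[[s]] <- data.frame(
      series_id = ids[s], timepoint = seq_len(nt), days = seriesTimes(ser),
      image = ipath, mask = mpath, volume_mm3 = av,
      label = noduleLabel(ser), split = unname(splits[ids[s]]),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (writeOut) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(series = seriesList, manifest = manifest, split = splits)
}
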