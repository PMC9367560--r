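# Preprocessing: raw CT volume + VOI mask -> normalized fixed-size nodule
# patch and segmented volume, assembled per nodule into a FollowUpSeries.

#' Wrap an array or NIfTI image as a CTVolume
#'
#' @param x 3D array or `RNifti` image.
#' @param spacing voxel spacing in mm; taken from the NIfTI header when `x`
#'   is a NIfTI image.
#' @return a [CTVolume-class].
#' @export
asCTVolume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "niftiImage")) {
    spacing <- RNifti::pixdim(x)[1:3]
    x <- array(as.numeric(x), dim = dim(x))
  }
  new("CTVolume", voxels = array(as.numeric(x), dim = dim(x)),
      spacing = as.numeric(spacing))
}

#' Read a NIfTI volume as CTVolume
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return a [CTVolume-class].
#' @export
readCTVolume <- function(path) asCTVolume(RNifti::readNifti(path))

#' Write a CTVolume as NIfTI
#' @param vol a [CTVolume-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeCTVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a CT volume to isotropic spacing
#'
#' Interpolates the volume onto a grid with `targetMm` spacing on all axes,
#' preserving the physical extent (trilinear for images, nearest-neighbor
#' for masks). Voxel centers are aligned so that an already-isotropic volume
#' passes through unchanged.
#'
#' @param vol a [CTVolume-class].
#' @param targetMm target spacing, mm.
#' @param method `"trilinear"` or `"nearest"`.
#' @return a resampled [CTVolume-class].
#' @export
resampleIsotropic <- function(vol, targetMm = 1,
                              method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (targetMm <= 0) stop("target spacing must be positive")
  sp <- vol@spacing
  if (any(sp <= 0)) stop("non-positive voxel spacing")
  d <- dim(vol@voxels)
  if (all(abs(sp - targetMm) < 1e-12)) return(vol)
  nd <- pmax(1L, as.integer(round(d * sp / targetMm)))
  # fractional source index (1-based) of each target voxel center
  fi <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 0.5) * targetMm) / sp[a] + 0.5
  })
  A <- vol@voxels
  if (method == "nearest") {
    ix <- lapply(1:3, function(a) pmin(pmax(round(fi[[a]]), 1L), d[a]))
    out <- A[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(fi[[a]]), 1L), d[a]))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
    w <- lapply(1:3, function(a) pmin(pmax(fi[[a]] - lo[[a]], 0), 1))
    out <- array(0, dim = nd)
    for (cz in 0:1) {
      kz <- if (cz == 0) lo[[3]] else hi[[3]]
      wz <- if (cz == 0) 1 - w[[3]] else w[[3]]
      for (cy in 0:1) {
        ky <- if (cy == 0) lo[[2]] else hi[[2]]
        wy <- if (cy == 0) 1 - w[[2]] else w[[2]]
        for (cx in 0:1) {
          kx <- if (cx == 0) lo[[1]] else hi[[1]]
          wx <- if (cx == 0) 1 - w[[1]] else w[[1]]
          wt <- outer(outer(wx, wy), wz)
          if (all(wt == 0)) next
          out <- out + wt * A[kx, ky, kz, drop = FALSE]
        }
      }
    }
  }
  new("CTVolume", voxels = out, spacing = rep(targetMm, 3))
}

#' Clip HU values and min-max normalize to \[0, 1\]
#'
#' `out = (clip(hu, -1000, 400) + 1000) / 1400`, so -1000 HU maps to exactly
#' 0, 400 HU to exactly 1 and -300 HU to 0.5.
#'
#' @param vol a [CTVolume-class] or plain array of HU values.
#' @return same type as the input, values in \[0, 1\].
#' @export
clipNormalize <- function(vol) {
  f <- function(x) (pmin(pmax(x, -1000), 400) + 1000) / 1400
  if (is(vol, "CTVolume")) {
    new("CTVolume", voxels = array(f(vol@voxels), dim(vol@voxels)),
        spacing = vol@spacing)
  } else {
    out <- f(vol)
    if (!is.null(dim(vol))) dim(out) <- dim(vol)
    out
  }
}

#' Segmented nodule volume in mm^3
#'
#' Foreground voxel count times the voxel volume.
#'
#' @param mask a [CTVolume-class] (binary voxels) or logical/numeric array.
#' @param spacing voxel spacing, mm; taken from the mask when it is a
#'   [CTVolume-class].
#' @return numeric(1), mm^3.
#' @export
maskVolumeMm3 <- function(mask, spacing = NULL) {
  if (is(mask, "CTVolume")) {
    spacing <- mask@spacing
    mask <- mask@voxels
  }
  if (is.null(spacing)) stop("spacing required for a plain array mask")
  n <- sum(mask > 0)
  if (n == 0) stop("empty VOI")
  n * prod(spacing)
}

#' Extract a fixed-size patch centered on the nodule
#'
#' Cubic crop of `size` voxels centered on the mask's center of mass
#' (rounded to the nearest voxel); regions outside the volume are padded
#' with 0 (the normalized value of air).
#'
#' @param vol a normalized, isotropic [CTVolume-class].
#' @param mask the paired VOI mask ([CTVolume-class] or array).
#' @param size patch edge length in voxels (default 32).
#' @return 3D array `size^3`.
#' @export
extractPatch <- function(vol, mask, size = 32L) {
  A <- vol@voxels
  m <- if (is(mask, "CTVolume")) mask@voxels else mask
  if (!all(dim(A) == dim(m))) stop("volume and mask shapes differ")
  fg <- which(m > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty VOI")
  ctr <- round(colMeans(fg))
  out <- array(0, dim = rep(size, 3L))
  start <- ctr - size %/% 2 + 1L
  src <- lapply(1:3, function(a) {
    i <- start[a]:(start[a] + size - 1L)
    ok <- i >= 1L & i <= dim(A)[a]
    list(src = i[ok], dst = which(ok))
  })
  out[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    A[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  out
}

# shared assembly used by buildSeries and the manifest loader
assembleSeries <- function(seriesId, times, images, masks, label,
                           targetMm = 1, patchSize = 32L) {
  pat <- vector("list", length(times))
  vol <- numeric(length(times))
  for (i in seq_along(times)) {
    img <- resampleIsotropic(images[[i]], targetMm, "trilinear")
    msk <- resampleIsotropic(masks[[i]], targetMm, "nearest")
    nrm <- clipNormalize(img)
    pat[[i]] <- extractPatch(nrm, msk, patchSize)
    vol[i] <- maskVolumeMm3(msk)
  }
  new("FollowUpSeries", seriesId = seriesId, times = as.numeric(times),
      patches = pat, volumes = vol,
      label = if (is.na(label)) NA_character_ else label)
}

#' Build a FollowUpSeries from dated scans
#'
#' Sorts scans by acquisition date, converts dates to days since the
#' earliest scan, and runs the preprocessing chain per scan: isotropic
#' resampling (trilinear image / nearest mask), HU clip + normalization,
#' patch extraction, and VOI volume measurement.
#'
#' Series with fewer than two scans are rejected, as are two-scan series
#' whose interval is below 30 days (the minimum follow-up interval of the
#' study design).
#'
#' @param scans list; each element a list with `date` (ISO-8601 string or
#'   `Date`), `image` ([CTVolume-class]) and `mask` ([CTVolume-class]).
#' @param label `"IA"`, `"non-IA"` or `NA`.
#' @param seriesId identifier.
#' @param targetMm isotropic spacing, mm.
#' @param patchSize patch edge, voxels.
#' @return a [FollowUpSeries-class].
#' @export
buildSeries <- function(scans, label = NA_character_, seriesId = "S1",
                        targetMm = 1, patchSize = 32L) {
  if (length(scans) < 2L) stop("insufficient time points")
  dates <- as.Date(vapply(scans, function(s) as.character(s$date), ""))
  if (anyDuplicated(dates)) stop("scan dates must be distinct")
  ord <- order(dates)
  scans <- scans[ord]
  dates <- dates[ord]
  times <- as.numeric(dates - dates[1])
  if (length(times) == 2L && times[2] < 30) stop("interval below 30 days")
  assembleSeries(seriesId, times,
                 lapply(scans, `[[`, "image"), lapply(scans, `[[`, "mask"),
                 label, targetMm, patchSize)
}

#' Load follow-up series from a dataset manifest
#'
#' Reads the CSV manifest written by [generateDataset()] (columns
#' `series_id, timepoint, days, image, mask, volume_mm3, label, split`),
#' loads the NIfTI volumes and runs the full preprocessing chain.
#'
#' @param manifest path to `manifest.csv` or a data.frame.
#' @param dir directory holding the NIfTI files (default: the manifest's
#'   directory).
#' @param split optional subset, e.g. `"test"`.
#' @param targetMm,patchSize preprocessing geometry.
#' @return named list of [FollowUpSeries-class].
#' @export
loadSeriesFromManifest <- function(manifest, dir = NULL, split = NULL,
                                   targetMm = 1, patchSize = 32L) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(dir)) stop("dir required when manifest is a data.frame")
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  ids <- unique(manifest$series_id)
  out <- lapply(ids, function(id) {
    rows <- manifest[manifest$series_id == id, ]
    rows <- rows[order(rows$days), ]
    assembleSeries(
      id, rows$days,
      lapply(rows$image, function(p) readCTVolume(file.path(dir, p))),
      lapply(rows$mask, function(p) readCTVolume(file.path(dir, p))),
      rows$label[1], targetMm, patchSize
    )
  })
  names(out) <- ids
  out
}
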