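# Gradient saliency: which voxels of which time point drive the final-step
# IA probability. The gradient is obtained by running the trained model in
# inference mode and backpropagating from the final-step output through the
# SimTA stack and the encoder down to the input voxels.

# gradients of the final-step output w.r.t. every patch of the series;
# returns array (s, s, s, 1, T)
.saliencyGradAll <- function(model, series, target = "probability") {
  x <- patchArray(patches(series))
  ef <- encoderForward(model@encoder, x, train = FALSE)
  fwd <- vistaSequenceForward(model, ef$feat, seriesTimes(series),
                              train = FALSE)
  Tn <- length(fwd$logits)
  dlog <- numeric(Tn)
  pT <- fwd$perStep[Tn]
  dlog[Tn] <- if (target == "probability") pT * (1 - pT) else 1
  bk <- vistaSequenceBackward(model, fwd, dlog)
  eb <- encoderBackward(model@encoder, ef$caches, bk$dfeat, needDx = TRUE)
  eb$dx
}

#' Gradient saliency map for one time point
#'
#' Backpropagates the final-step IA probability of a series through the
#' whole network to the voxels of the patch at time point `k`; the absolute
#' gradient is clipped to \[0, `clip`\] for display (the raw magnitudes are
#' kept in the `raw` slot).
#'
#' @param model a trained [VistaModel-class].
#' @param series a [FollowUpSeries-class].
#' @param k time point index (1-based), `k <= nTimepoints(series)`.
#' @param clip display clip value (default 0.01).
#' @param target differentiate the sigmoid `"probability"` (default) or the
#'   pre-sigmoid `"logit"`.
#' @return a [SaliencyMap-class].
#' @export
saliencyMap <- function(model, series, k, clip = 0.01,
                        target = c("probability", "logit")) {
  target <- match.arg(target)
  if (k < 1 || k > nTimepoints(series)) stop("timepoint out of range")
  dx <- .saliencyGradAll(model, series, target)
  raw <- abs(array(dx[, , , 1, k], dim = dim(dx)[1:3]))
  new("SaliencyMap", values = pmin(raw, clip), raw = raw,
      timepoint = as.integer(k), clip = clip)
}

#' Saliency maps for all time points of a series
#'
#' One backward pass; the list is suitable for [saliencyMontage()].
#'
#' @inheritParams saliencyMap
#' @return list of [SaliencyMap-class], one per time point.
#' @export
saliencyMaps <- function(model, series, clip = 0.01,
                         target = c("probability", "logit")) {
  target <- match.arg(target)
  dx <- .saliencyGradAll(model, series, target)
  lapply(seq_len(nTimepoints(series)), function(k) {
    raw <- abs(array(dx[, , , 1, k], dim = dim(dx)[1:3]))
    new("SaliencyMap", values = pmin(raw, clip), raw = raw,
        timepoint = as.integer(k), clip = clip)
  })
}

.heatColormap <- grDevices::colorRamp(
  c("#00004B", "#0000FF", "#00FFFF", "#FFFF00", "#FF0000")
)

# grayscale slice + heatmap slice + alpha overlay, each as h x w x 3 arrays
.renderPanels <- function(patchSlice, mapSlice, clip) {
  g <- pmin(pmax(patchSlice, 0), 1)
  v <- pmin(pmax(mapSlice / clip, 0), 1)
  gray <- array(rep(g, 3), dim = c(dim(g), 3))
  colv <- .heatColormap(as.vector(v)) / 255
  heat <- array(colv, dim = c(dim(v), 3))
  a <- array(rep(0.6 * v, 3), dim = c(dim(v), 3))
  over <- (1 - a) * gray + a * heat
  list(ct = gray, heat = heat, overlay = over)
}

#' Overlay a saliency map on a CT slice and write a PNG
#'
#' Renders a three-panel image (CT slice, heatmap, overlay) for one time
#' point. The color scale is fixed to \[0, `clip`\] so panels are comparable
#' across time points.
#'
#' @param patch 3D normalized patch array.
#' @param map a [SaliencyMap-class] of the same shape.
#' @param file output PNG path.
#' @param axis slicing axis (default 3, axial).
#' @param index slice index; default the central slice (the patch is
#'   centered on the nodule by construction).
#' @return `file`, invisibly.
#' @export
overlayPNG <- function(patch, map, file, axis = 3L, index = NULL) {
  stopifnot(all(dim(patch) == dim(map@values)))
  if (is.null(index)) index <- (dim(patch)[axis] + 1) %/% 2
  sl <- function(A) switch(axis, A[index, , ], A[, index, ], A[, , index])
  pan <- .renderPanels(sl(patch), sl(map@values), map@clip)
  img <- abind3(pan$ct, pan$heat, pan$overlay)
  png::writePNG(img, file)
  invisible(file)
}

#' Saliency montage across a whole series
#'
#' One column per time point, three rows (CT slice, heatmap, overlay), with
#' a single color scale across the series.
#'
#' @param series a [FollowUpSeries-class].
#' @param maps list of [SaliencyMap-class] from [saliencyMaps()].
#' @param file output PNG path.
#' @param axis,index as in [overlayPNG()].
#' @return `file`, invisibly.
#' @export
saliencyMontage <- function(series, maps, file, axis = 3L, index = NULL) {
  ps <- patches(series)
  if (is.null(index)) index <- (dim(ps[[1]])[axis] + 1) %/% 2
  sl <- function(A) switch(axis, A[index, , ], A[, index, ], A[, , index])
  cols <- lapply(seq_along(ps), function(k) {
    pan <- .renderPanels(sl(ps[[k]]), sl(maps[[k]]@values), maps[[k]]@clip)
    abind3(pan$ct, pan$heat, pan$overlay)
  })
  h <- dim(cols[[1]])[1]
  w <- dim(cols[[1]])[2]
  img <- array(0, dim = c(h, w * length(cols), 3))
  for (k in seq_along(cols)) {
    img[, ((k - 1) * w + 1):(k * w), ] <- cols[[k]]
  }
  png::writePNG(img, file)
  invisible(file)
}

# stack three h x w x 3 panels vertically with a 1-px separator
abind3 <- function(...) {
  panels <- list(...)
  h <- dim(panels[[1]])[1]
  w <- dim(panels[[1]])[2]
  n <- length(panels)
  out <- array(1, dim = c(h * n + (n - 1), w, 3))
  for (i in seq_len(n)) {
    r0 <- (i - 1) * (h + 1)
    out[(r0 + 1):(r0 + h), , ] <- panels[[i]]
  }
  out
}
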