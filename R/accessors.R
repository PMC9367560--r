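#' @rdname seriesId
#' @export
setMethod("seriesId", "FollowUpSeries", function(x) x@seriesId)

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "FollowUpSeries", function(x) x@times)

#' @rdname patches
#' @export
setMethod("patches", "FollowUpSeries", function(x) x@patches)

#' @rdname volumes
#' @export
setMethod("volumes", "FollowUpSeries", function(x) x@volumes)

#' @rdname noduleLabel
#' @export
setMethod("noduleLabel", "FollowUpSeries", function(x) x@label)

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "FollowUpSeries", function(x) length(x@times))

setMethod("show", "FollowUpSeries", function(object) {
  cat(sprintf(
    "FollowUpSeries '%s': %d time points over %g days, label %s\n",
    object@seriesId, length(object@times), max(object@times),
    ifelse(is.na(object@label), "<unknown>", object@label)
  ))
  cat(sprintf("  times (days): %s\n", paste(object@times, collapse = ", ")))
  cat(sprintf("  volumes (mm^3): %s\n",
              paste(signif(object@volumes, 4), collapse = ", ")))
  shp <- dim(object@patches[[1]])
  cat(sprintf("  patch shape: %s\n", paste(shp, collapse = " x ")))
})

setMethod("show", "CTVolume", function(object) {
  cat(sprintf("CTVolume %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(object@voxels), collapse = " x "),
              paste(object@spacing, collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "GrowthParams: %s, v0 = %.1f mm^3, doubling time = %s days,\n  solid fraction %.2f -> %.2f, noise %.0f HU, background %.0f HU\n",
    object@modelKind, object@v0,
    ifelse(is.finite(object@dtDouble), sprintf("%.0f", object@dtDouble), "Inf"),
    object@solid0, object@solidEnd, object@noiseSd, object@backgroundHu
  ))
})

setMethod("show", "VDTResult", function(object) {
  cat(sprintf("VDTResult: VDT = %s days, 1/VDT = %.6g per day\n",
              ifelse(is.finite(object@vdtDays),
                     sprintf("%.1f", object@vdtDays), "Inf"),
              object@invVdt))
})

setMethod("show", "MetricsReport", function(object) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat("MetricsReport\n")
  cat(sprintf("  AUC %s | acc %s | prec %s | sens %s | spec %s | F1 %s\n",
              fmt(object@auc), fmt(object@accuracy), fmt(object@precision),
              fmt(object@sensitivity), fmt(object@specificity),
              fmt(object@f1)))
  cat(sprintf("  threshold %.4g; counts TP %d FP %d TN %d FN %d\n",
              object@threshold, object@counts["TP"], object@counts["FP"],
              object@counts["TN"], object@counts["FN"]))
})

setMethod("show", "IAPrediction", function(object) {
  cat(sprintf("IAPrediction: p(IA) = %.4f (per step: %s)\n", object@pIA,
              paste(sprintf("%.3f", object@perStep), collapse = ", ")))
})

setMethod("show", "VistaModel", function(object) {
  cat(sprintf(
    "VistaModel: %d-stage 3D CNN encoder (D = %d) + %d SimTA layer(s), tau = %g days\n",
    length(object@encoder$stages),
    object@config$dim, object@config$nLayers, object@config$timeScale
  ))
  cat(sprintf("  trainable parameters: %d (temporal module: %d)\n",
              countParams(object), countParams(object, includeBackbone = FALSE)))
})

setMethod("show", "CNNScorer", function(object) {
  cat(sprintf("CNNScorer (training policy: %s), %d parameters\n",
              object@config$trainPolicy %||% "<untrained>",
              countParams(object)))
})

setMethod("show", "CNNLSTMModel", function(object) {
  cat(sprintf(
    "CNNLSTMModel: CNN encoder (D = %d) + LSTM (hidden %d); %d parameters (recurrent module: %d)\n",
    object@config$dim, object@config$hidden, countParams(object),
    countParams(object, includeBackbone = FALSE)
  ))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
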