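#' @import methods
NULL

#' Follow-up CT series of one nodule
#'
#' The unit of prediction: an ordered set of CT examinations of a single lung
#' nodule. Each time point carries a normalized, fixed-size 3D image patch
#' centered on the nodule and the segmented nodule volume; the series carries
#' at most one pathology label (invasive adenocarcinoma versus not).
#'
#' @slot seriesId character(1) identifier.
#' @slot times numeric, days since the first scan; strictly increasing with
#'   `times[1] == 0`.
#' @slot patches list of 3D numeric arrays (values in \[0, 1\]), one per time
#'   point, all with identical cubic shape.
#' @slot volumes numeric, segmented nodule volume in mm^3 per time point.
#' @slot label character(1), `"IA"`, `"non-IA"`, or `NA` when unknown
#'   (inference time).
#'
#' @seealso [buildSeries()], [sampleSeries()], [predictIA()]
#' @export
setClass("FollowUpSeries",
  representation(
    seriesId = "character",
    times = "numeric",
    patches = "list",
    volumes = "numeric",
    label = "character"
  ),
  prototype(seriesId = NA_character_, label = NA_character_)
)

setValidity("FollowUpSeries", function(object) {
  n <- length(object@times)
  if (n < 1L) return("series must contain at least one time point")
  if (length(object@patches) != n || length(object@volumes) != n) {
    return("times, patches and volumes must have equal length")
  }
  if (object@times[1] != 0) return("times must start at 0")
  if (n > 1L && any(diff(object@times) <= 0)) {
    return("times must be strictly increasing")
  }
  if (length(object@label) != 1L) return("exactly one label per series")
  if (!is.na(object@label) && !object@label %in% c("IA", "non-IA")) {
    return("label must be 'IA', 'non-IA' or NA")
  }
  shp <- lapply(object@patches, dim)
  if (n > 1L && length(unique(vapply(shp, paste, "", collapse = "x"))) > 1L) {
    return("all patches must share one shape")
  }
  TRUE
})

#' CT volume with voxel spacing
#'
#' A plain 3D voxel grid plus its physical voxel spacing in mm. Used both for
#' HU-valued images and for binary VOI masks (0/1 voxels).
#'
#' @slot voxels 3D numeric array.
#' @slot spacing numeric(3), mm per voxel along each axis; all positive.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric")
)

setValidity("CTVolume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be three positive numbers")
  }
  TRUE
})

#' Growth model parameters for one synthetic nodule
#'
#' @slot modelKind `"exponential"` or `"gompertz"`.
#' @slot v0 initial nodule volume, mm^3 (> 0).
#' @slot dtDouble intrinsic volume doubling time, days (> 0; `Inf` encodes a
#'   static nodule).
#' @slot solid0,solidEnd solid-core volume fraction in \[0, 1\] at the start
#'   and end of the follow-up series, with `solid0 <= solidEnd`.
#' @slot noiseSd additive image noise, HU (>= 0).
#' @slot backgroundHu lung parenchyma attenuation, HU.
#' @export
setClass("GrowthParams",
  representation(
    modelKind = "character", v0 = "numeric", dtDouble = "numeric",
    solid0 = "numeric", solidEnd = "numeric", noiseSd = "numeric",
    backgroundHu = "numeric"
  )
)

setValidity("GrowthParams", function(object) {
  if (!object@modelKind %in% c("exponential", "gompertz")) {
    return("modelKind must be 'exponential' or 'gompertz'")
  }
  if (object@v0 <= 0) return("v0 must be positive")
  if (object@dtDouble <= 0) return("dtDouble must be positive (Inf allowed)")
  if (object@solid0 < 0 || object@solidEnd > 1 ||
      object@solid0 > object@solidEnd) {
    return("need 0 <= solid0 <= solidEnd <= 1")
  }
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})

#' Volume doubling time of a nodule
#'
#' @slot vdtDays doubling time in days; `Inf` for a static nodule, negative
#'   for shrinkage.
#' @slot invVdt reciprocal doubling time (1/day), the ranking score used by
#'   the size-based baseline; 0 for a static nodule.
#' @export
setClass("VDTResult",
  representation(vdtDays = "numeric", invVdt = "numeric")
)

#' Score cutoff rule
#'
#' @slot threshold numeric score cutoff.
#' @slot direction `">="` (score at or above threshold is positive) or `"<="`.
#' @slot origin `"fixed_400_days"` or `"best_youden"`.
#' @export
setClass("CutoffRule",
  representation(threshold = "numeric", direction = "character",
                 origin = "character")
)

setValidity("CutoffRule", function(object) {
  if (!object@origin %in% c("fixed_400_days", "best_youden")) {
    return("origin must be 'fixed_400_days' or 'best_youden'")
  }
  if (!object@direction %in% c(">=", "<=")) {
    return("direction must be '>=' or '<='")
  }
  TRUE
})

#' Classifier evaluation report
#'
#' Threshold-free (AUC, ROC curve) and thresholded (accuracy, precision,
#' sensitivity, specificity, F1, Youden index) evaluation of a scorer.
#' Metrics with a zero denominator are reported as `NA`, never coerced to 0.
#'
#' @slot auc numeric(1) area under the ROC curve (midrank/trapezoid; equals
#'   pairwise concordance with ties counted 1/2).
#' @slot accuracy,precision,sensitivity,specificity,f1 numeric(1) in \[0, 1\]
#'   or `NA` when undefined.
#' @slot youden numeric(1), sensitivity + specificity - 1.
#' @slot threshold numeric(1) score cutoff used (score >= threshold positive).
#' @slot counts integer(4) named TP, FP, TN, FN.
#' @slot roc data.frame with columns `fpr`, `tpr` from (0,0) to (1,1).
#' @export
setClass("MetricsReport",
  representation(
    auc = "numeric", accuracy = "numeric", precision = "numeric",
    sensitivity = "numeric", specificity = "numeric", f1 = "numeric",
    youden = "numeric", threshold = "numeric", counts = "integer",
    roc = "data.frame"
  ),
  prototype(roc = data.frame(fpr = numeric(0), tpr = numeric(0)))
)

#' Invasiveness prediction for one series
#'
#' @slot pIA probability that the nodule is invasive adenocarcinoma, taken at
#'   the last time point.
#' @slot perStep probability at every prefix of the series (the prediction the
#'   model would have made at each examination).
#' @export
setClass("IAPrediction",
  representation(pIA = "numeric", perStep = "numeric")
)

setValidity("IAPrediction", function(object) {
  p <- c(object@pIA, object@perStep)
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("probabilities must be in [0,1]")
  TRUE
})

#' Gradient saliency map for one time point
#'
#' Absolute gradient of the final-step IA probability with respect to the
#' voxels of one input patch, clipped for display.
#'
#' @slot values 3D array of clipped values in \[0, clip\].
#' @slot raw 3D array of unclipped absolute gradients.
#' @slot timepoint integer index of the patch differentiated.
#' @slot clip numeric(1) upper clip value (default 0.01).
#' @export
setClass("SaliencyMap",
  representation(values = "array", raw = "array", timepoint = "integer",
                 clip = "numeric")
)

setValidity("SaliencyMap", function(object) {
  if (any(object@values < 0) || any(object@values > object@clip + 1e-12)) {
    return("values must lie in [0, clip]")
  }
  TRUE
})

# --- model containers ------------------------------------------------------

#' ViSTA model: 3D CNN encoder + SimTA temporal attention + IA head
#'
#' @slot encoder list of encoder parameters and running statistics.
#' @slot simta list of SimTA layer parameter lists.
#' @slot head list with weight vector `w` and bias `b`.
#' @slot config list of hyperparameters (dim, nLayers, timeScale, dropout,
#'   channels, patchSize, ffnMult, seed).
#' @export
setClass("VistaModel",
  representation(encoder = "list", simta = "list", head = "list",
                 config = "list")
)

#' Static CNN scorer (single time point)
#'
#' @slot encoder list of encoder parameters.
#' @slot head list with `w`, `b`.
#' @slot config list; `trainPolicy` records which time points trained it
#'   (`first_only`, `last_only`, `all_points`).
#' @export
setClass("CNNScorer",
  representation(encoder = "list", head = "list", config = "list")
)

#' CNN+LSTM baseline (interval-blind sequence model)
#'
#' @slot encoder list of encoder parameters.
#' @slot lstm list of recurrent parameters.
#' @slot head list with `w`, `b`.
#' @slot config list of hyperparameters.
#' @export
setClass("CNNLSTMModel",
  representation(encoder = "list", lstm = "list", head = "list",
                 config = "list")
)
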