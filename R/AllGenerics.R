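#' Series identifier
#' @param x a [FollowUpSeries-class].
#' @return character(1).
#' @export
setGeneric("seriesId", function(x) standardGeneric("seriesId"))

#' Scan times in days since the first examination
#' @param x a [FollowUpSeries-class].
#' @return numeric vector, strictly increasing, starting at 0.
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' Nodule patches of a series
#' @param x a [FollowUpSeries-class].
#' @return list of 3D arrays.
#' @export
setGeneric("patches", function(x) standardGeneric("patches"))

#' Segmented nodule volumes (mm^3) of a series
#' @param x a [FollowUpSeries-class].
#' @return numeric vector.
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' Pathology label of a series
#' @param x a [FollowUpSeries-class].
#' @return `"IA"`, `"non-IA"` or `NA`.
#' @export
setGeneric("noduleLabel", function(x) standardGeneric("noduleLabel"))

#' Number of time points
#' @param x a [FollowUpSeries-class].
#' @return integer(1).
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' Predict invasive-adenocarcinoma status
#'
#' Runs a trained (or freshly initialized) model on one follow-up series in
#' inference mode and returns the IA probability.
#'
#' @param model a [VistaModel-class], [CNNScorer-class] or
#'   [CNNLSTMModel-class].
#' @param series a [FollowUpSeries-class].
#' @param ... method-specific options; `CNNScorer` accepts
#'   `at = c("last", "first")` selecting the evaluated time point.
#' @return an [IAPrediction-class].
#' @export
setGeneric("predictIA", function(model, series, ...)
  standardGeneric("predictIA"))

#' Count trainable parameters
#'
#' @param model a model object.
#' @param includeBackbone logical; when `FALSE` the shared CNN encoder is
#'   excluded, leaving only the temporal/classification module, which is how
#'   the temporal modules of different architectures are compared.
#' @return integer(1) total number of trainable scalars.
#' @export
setGeneric("countParams", function(model, includeBackbone = TRUE)
  standardGeneric("countParams"))

#' Train a model
#'
#' @param model a model object (its class selects the architecture-specific
#'   loop).
#' @param data list with elements `train` and `val`, each a list of labelled
#'   [FollowUpSeries-class] objects.
#' @param cfg a [trainConfig()] list.
#' @return the trained model; the per-epoch history (`epoch`, `lr`, `loss`,
#'   `val_auc`) is attached as attribute `"history"`.
#' @export
setGeneric("trainModel", function(model, data, cfg) standardGeneric("trainModel"))
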