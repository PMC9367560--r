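# Model checkpointing: one serialized weight file plus a human-readable JSON
# hyperparameter sidecar.

#' Save a model checkpoint
#'
#' Writes the full model object to `path` and a JSON sidecar
#' (`<path>.json`) holding the model class and its hyperparameter
#' configuration, so a checkpoint can be identified without deserializing.
#'
#' @param model a [VistaModel-class], [CNNScorer-class] or
#'   [CNNLSTMModel-class].
#' @param path output file path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  side <- c(list(class = class(model)[1]), model@config)
  side <- side[!vapply(side, is.null, TRUE)]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path passed to [saveModel()].
#' @return the model object.
#' @export
loadModel <- function(path) {
  readRDS(path)
}
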