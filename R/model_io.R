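#' Serialize a trained model to versioned JSON
#'
#' @param model A `miln_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = "hrdmiln-model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("hrdmiln")),
    feature_names = model$feature_names,
    concepts = model$concepts$concepts,
    scales = model$concepts$scales,
    threshold = model$threshold,
    pro = model$pro,
    bounds = list(min = as.list(model$bounds$min),
                  max = as.list(model$bounds$max)),
    training_log = model$training_log)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON document.
#' @return A `miln_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hrdmiln-model")) {
    stop("not a hrdmiln model file: ", path)
  }
  bounds <- structure(list(min = unlist(doc$bounds$min),
                           max = unlist(doc$bounds$max)),
                      class = "miln_bounds")
  structure(list(
    concepts = miln_concepts(as.matrix(doc$concepts), doc$scales),
    threshold = doc$threshold,
    pro = doc$pro,
    bounds = bounds,
    feature_names = doc$feature_names,
    training_log = doc$training_log),
    class = "miln_model")
}
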