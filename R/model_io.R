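# Model persistence: one self-describing archive holding the reference
# vectors, labels, FKNN parameters, fusion weights and property tables.

#' Write a trained cascade model to disk
#'
#' @param model A \code{\link{train_cascade}} model.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Read a cascade model written by \code{\link{write_model}}
#'
#' @param path Model file path.
#' @return A \code{cascade_model}.
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cascade_model") || is.null(model$version)) {
    stop("not a cascade model file: ", path)
  }
  model
}
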