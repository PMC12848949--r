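# Checkpoint persistence: a single self-describing, versioned RDS container.

CHECKPOINT_FORMAT <- "dginet-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save a fitted model to a checkpoint file
#'
#' The checkpoint is a single versioned container holding the configuration,
#' all parameter matrices, the node map, the training-edge table, and the
#' full training history; reloading reproduces identical predictions.
#'
#' @param fit A `dgi_fit`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "dgi_fit"))
  saveRDS(list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
               fit = fit), path)
  invisible(path)
}

#' Load a fitted model from a checkpoint file
#'
#' @param path Path written by [write_checkpoint()].
#' @return The `dgi_fit`.
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, CHECKPOINT_FORMAT)) {
    stop("not a model checkpoint: ", path)
  }
  if (obj$version > CHECKPOINT_VERSION) {
    stop("checkpoint version ", obj$version, " is newer than this package supports")
  }
  obj$fit
}
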