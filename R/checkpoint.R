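#' Save and load stack checkpoints
#'
#' A checkpoint is an RDS container holding a format tag, the stack
#' configuration (input size and per-layer hyper-parameters) and the weight
#' matrices; [loadCheckpoint()] rebuilds the stack through the validated
#' constructor path, so a round trip is bit-identical in the weights.
#' Optionally the training trace is stored alongside.
#'
#' @param stack an [MRStack-class] (or an [MRTraining-class], whose stack
#'   and trace are both stored).
#' @param path file path to write.
#' @return `path`, invisibly, for `saveCheckpoint`; an [MRStack-class]
#'   (with attribute `"trace"` if one was stored) for `loadCheckpoint`.
#' @export
saveCheckpoint <- function(stack, path) {
  trace <- NULL
  if (is(stack, "MRTraining")) {
    trace <- stack@trace
    stack <- stack@stack
  }
  stopifnot(is(stack, "MRStack"))
  payload <- list(
    format = "mrnet-checkpoint-1",
    inputSize = stack@inputSize,
    layers = lapply(stack@layers, function(l) list(
      weights = l@weights,
      receptiveField = l@receptiveField,
      bankShape = l@bankShape,
      dilationGap = l@dilationGap,
      learningRate = l@learningRate,
      topology = l@topology,
      frozen = l@frozen)),
    trace = trace)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  p <- readRDS(path)
  if (!identical(p$format, "mrnet-checkpoint-1"))
    stop("not an mrnet checkpoint file")
  st <- MRStack(
    inputSize = p$inputSize,
    receptiveFields = lapply(p$layers, `[[`, "receptiveField"),
    bankShapes = lapply(p$layers, `[[`, "bankShape"),
    dilationGaps = lapply(p$layers, `[[`, "dilationGap"),
    learningRates = vapply(p$layers, `[[`, numeric(1), "learningRate"),
    topology = p$layers[[1L]]$topology)
  for (L in seq_along(p$layers)) {
    st@layers[[L]]@weights <- p$layers[[L]]$weights
    st@layers[[L]]@frozen <- p$layers[[L]]$frozen
  }
  validObject(st)
  if (!is.null(p$trace)) attr(st, "trace") <- p$trace
  st
}
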