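#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))

#' Number of layers in a stack
#' @param object an [MRStack-class].
#' @return integer(1).
#' @aliases nLayers
#' @export
setMethod("nLayers", "MRStack", function(object) length(object@layers))

#' @export
setGeneric("bankShape", function(object, ...) standardGeneric("bankShape"))

#' Filter-bank shape accessors
#' @param object an [MRLayer-class] or [MRStack-class].
#' @param layer layer index (for stacks).
#' @param ... unused.
#' @return integer(2), or a list of them for a whole stack.
#' @aliases bankShape
#' @export
setMethod("bankShape", "MRLayer", function(object, ...) object@bankShape)

#' @rdname bankShape-MRLayer-method
#' @export
setMethod("bankShape", "MRStack", function(object, layer = NULL, ...) {
  if (is.null(layer)) lapply(object@layers, bankShape)
  else bankShape(object@layers[[layer]])
})

#' @export
setGeneric("filterWeights", function(object, ...) standardGeneric("filterWeights"))

#' Filter-bank weight accessors
#' @param object an [MRLayer-class] or [MRStack-class].
#' @param layer layer index (for stacks).
#' @param ... unused.
#' @return the `j x i` weight matrix.
#' @aliases filterWeights
#' @export
setMethod("filterWeights", "MRLayer", function(object, ...) object@weights)

#' @rdname filterWeights-MRLayer-method
#' @export
setMethod("filterWeights", "MRStack", function(object, layer, ...)
  filterWeights(object@layers[[layer]]))

#' @export
setGeneric("filterWeights<-", function(object, ..., value)
  standardGeneric("filterWeights<-"))

#' @rdname filterWeights-MRLayer-method
#' @param value replacement weight matrix.
#' @export
setReplaceMethod("filterWeights", "MRLayer", function(object, ..., value) {
  object@weights <- value
  validObject(object)
  object
})

#' @rdname filterWeights-MRLayer-method
#' @export
setReplaceMethod("filterWeights", "MRStack", function(object, layer, ..., value) {
  filterWeights(object@layers[[layer]]) <- value
  validObject(object)
  object
})

#' @export
setGeneric("layerGeometry", function(object, layer) standardGeneric("layerGeometry"))

#' Geometry accessor
#' @param object an [MRStack-class].
#' @param layer layer index; if missing, the full list.
#' @return a [LayerGeometry-class] or list of them.
#' @aliases layerGeometry
#' @export
setMethod("layerGeometry", "MRStack", function(object, layer) {
  if (missing(layer)) object@geometry else object@geometry[[layer]]
})

#' @export
setGeneric("similarityTrace", function(object) standardGeneric("similarityTrace"))

#' Similarity trace accessor
#' @param object an [MRTraining-class].
#' @return data.frame with `iteration`, `layer`, `similarity`.
#' @aliases similarityTrace
#' @export
setMethod("similarityTrace", "MRTraining", function(object) object@trace)

#' @export
setGeneric("trainedStack", function(object) standardGeneric("trainedStack"))

#' Trained stack accessor
#' @param object an [MRTraining-class].
#' @return the trained [MRStack-class].
#' @aliases trainedStack
#' @export
setMethod("trainedStack", "MRTraining", function(object) object@stack)

setMethod("show", "MRLayer", function(object) {
  cat(sprintf("MRLayer: bank %d x %d (%d kernels of length %d), rf %d x %d, gap %d, alpha %s, %s%s\n",
              object@bankShape[1L], object@bankShape[2L],
              nrow(object@weights), ncol(object@weights),
              object@receptiveField[1L], object@receptiveField[2L],
              object@dilationGap[1L],
              format(object@learningRate), object@topology,
              if (object@frozen) " [frozen]" else ""))
})

setMethod("show", "MRStack", function(object) {
  cat(sprintf("MRStack: %d x %d input, %d layer(s)\n",
              object@inputSize[1L], object@inputSize[2L], length(object@layers)))
  for (L in seq_along(object@layers)) {
    g <- object@geometry[[L]]
    lay <- object@layers[[L]]
    cat(sprintf("  layer %d: grid %d x %d, patch length %d, bank %d x %d, output %d x %d, coverage %d px%s\n",
                L, g@gridDim[1L], g@gridDim[2L], g@patchLength,
                lay@bankShape[1L], lay@bankShape[2L],
                g@gridDim[1L] * lay@bankShape[1L],
                g@gridDim[2L] * lay@bankShape[2L],
                g@pixelCoverage, if (lay@frozen) " [frozen]" else ""))
  }
})

setMethod("show", "MRTraining", function(object) {
  cat(sprintf("MRTraining: %d layer(s), %s iterations, outcomes: %s\n",
              length(object@iterations),
              paste(object@iterations, collapse = "+"),
              paste(object@outcomes, collapse = ", ")))
  if (nrow(object@trace) > 0)
    cat(sprintf("  similarity: first %.3f, last %.3f (%d samples)\n",
                object@trace$similarity[1L],
                object@trace$similarity[nrow(object@trace)],
                nrow(object@trace)))
})

setMethod("show", "StoppingRule", function(object) {
  cat(sprintf("StoppingRule: threshold %g, EMA coefficient %g, burn-in %d\n",
              object@threshold, object@emaCoefficient, object@burnIn))
})

setMethod("show", "StreamPair", function(object) {
  cat(sprintf("StreamPair: %s, %d x %d, seed %d\n",
              object@spec$kind, object@spec$size[1L], object@spec$size[2L],
              object@spec$seed))
})
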