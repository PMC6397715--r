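#' @import methods
NULL

#' Layer geometry
#'
#' Describes how one layer's sliding windows gather elements from the grid
#' below it: the grid of window positions, the cell-block size (1x1 for the
#' image layer, otherwise the lower layer's filter-bank shape), the dilated
#' window extents, and a precomputed gather index map. Constructed by
#' [deriveGeometry()]; users normally never build one directly.
#'
#' @slot gridDim integer(2); window positions (rows, cols).
#' @slot cellBlock integer(2); elements per lower-grid cell.
#' @slot windowCells integer(2); receptive field extent in cells.
#' @slot cellStep integer(2); cells between consecutive gathered cells
#'   (dilation gap + 1; 1 means contiguous).
#' @slot patchLength integer(1); flattened patch length `i`.
#' @slot inputDim integer(2); dimensions of the grid the windows slide over.
#' @slot pixelCoverage integer(1); nominal side length in input pixels
#'   covered by one window.
#' @slot indexMap integer matrix `n x i`; `indexMap[p, k]` is the linear
#'   (column-major) index into the lower grid of element `k` of patch `p`.
#'   Patch elements are ordered row-major over
#'   (cell-row, cell-col, within-cell-row, within-cell-col); patches are
#'   ordered row-major over window positions.
#'
#' @aliases LayerGeometry
#' @exportClass LayerGeometry
setClass("LayerGeometry",
  representation(
    gridDim = "integer",
    cellBlock = "integer",
    windowCells = "integer",
    cellStep = "integer",
    patchLength = "integer",
    inputDim = "integer",
    pixelCoverage = "integer",
    indexMap = "matrix"
  )
)

setValidity("LayerGeometry", function(object) {
  msg <- character(0)
  for (s in c("gridDim", "cellBlock", "windowCells", "cellStep", "inputDim"))
    if (length(slot(object, s)) != 2L || any(slot(object, s) < 1L))
      msg <- c(msg, sprintf("'%s' must be two positive integers", s))
  if (length(msg)) return(msg)
  n <- prod(object@gridDim)
  if (!all(dim(object@indexMap) == c(n, object@patchLength)))
    msg <- c(msg, "indexMap dimensions disagree with gridDim/patchLength")
  if (nrow(object@indexMap) > 0 &&
      (min(object@indexMap) < 1L || max(object@indexMap) > prod(object@inputDim)))
    msg <- c(msg, "indexMap points outside the input grid")
  if (length(msg)) msg else TRUE
})

#' A single multi-resolution network layer
#'
#' Holds one layer's filter bank together with the hyper-parameters that
#' define its receptive-field geometry and learning behaviour. The filter
#' bank is a `j x i` matrix whose rows are kernels; kernel `k` (1-based)
#' sits at bank position (row `(k-1) %/% j_c`, column `(k-1) %% j_c`),
#' row-major. Bank rows are the coarse-to-fine axis: under the cumulative
#' inhibition topology every kernel is inhibited by all kernels in earlier
#' (and its own) bank rows, so later rows are pushed toward residual,
#' finer-grained structure.
#'
#' @slot weights numeric matrix `j x i`; the filter bank.
#' @slot receptiveField integer(2); window extent in lower-grid cells.
#' @slot bankShape integer(2); bank rows and columns `(j_r, j_c)`.
#' @slot dilationGap integer(2); cells skipped between consecutive gathered
#'   cells of a window (0 for contiguous windows).
#' @slot learningRate numeric(1); the update step size alpha (`NA` requests
#'   an automatic, input-energy scaled rate at training time).
#' @slot topology `"printed"` or `"strict_raster"`; see [inhibitionMask()].
#' @slot frozen logical(1); frozen layers receive no weight updates.
#'
#' @seealso [MRStack()], [inhibitionMask()], [weightDelta()]
#' @aliases MRLayer
#' @exportClass MRLayer
setClass("MRLayer",
  representation(
    weights = "matrix",
    receptiveField = "integer",
    bankShape = "integer",
    dilationGap = "integer",
    learningRate = "numeric",
    topology = "character",
    frozen = "logical"
  ),
  prototype(
    dilationGap = c(0L, 0L),
    learningRate = 5e-4,
    topology = "printed",
    frozen = FALSE
  )
)

setValidity("MRLayer", function(object) {
  msg <- character(0)
  if (length(object@receptiveField) != 2L || any(object@receptiveField < 1L))
    msg <- c(msg, "receptiveField must be two positive integers")
  if (length(object@bankShape) != 2L || any(object@bankShape < 1L))
    msg <- c(msg, "bankShape must be two positive integers")
  if (length(object@dilationGap) != 2L || any(object@dilationGap < 0L))
    msg <- c(msg, "dilationGap must be two non-negative integers")
  if (!is.na(object@learningRate) && object@learningRate < 0)
    msg <- c(msg, "learningRate must be >= 0 (or NA for automatic)")
  if (!object@topology %in% c("printed", "strict_raster"))
    msg <- c(msg, "topology must be 'printed' or 'strict_raster'")
  if (nrow(object@weights) != prod(object@bankShape))
    msg <- c(msg, "weights must have prod(bankShape) rows")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' A stack of multi-resolution network layers
#'
#' The full hierarchy: an input size, an ordered list of [MRLayer-class]
#' objects and the derived [LayerGeometry-class] for each. Layer 1 slides
#' contiguous windows over the raw image; each higher layer slides dilated
#' windows over the packed output grid of the layer below, so that nominal
#' receptive-field coverage grows toward the full image while kernels stay
#' small. Build with [MRStack()].
#'
#' @slot inputSize integer(2); input image size in pixels (rows, cols).
#' @slot layers list of [MRLayer-class].
#' @slot geometry list of [LayerGeometry-class], parallel to `layers`.
#'
#' @aliases MRStack
#' @exportClass MRStack
setClass("MRStack",
  representation(
    inputSize = "integer",
    layers = "list",
    geometry = "list"
  )
)

setValidity("MRStack", function(object) {
  msg <- character(0)
  if (length(object@inputSize) != 2L || any(object@inputSize < 1L))
    msg <- c(msg, "inputSize must be two positive integers")
  if (length(object@layers) != length(object@geometry))
    msg <- c(msg, "layers and geometry must have equal length")
  if (length(object@layers) == 0L)
    msg <- c(msg, "a stack needs at least one layer")
  if (length(msg)) return(msg)
  for (L in seq_along(object@layers)) {
    lay <- object@layers[[L]]
    geo <- object@geometry[[L]]
    if (!is(lay, "MRLayer")) return(sprintf("layer %d is not an MRLayer", L))
    if (!is(geo, "LayerGeometry")) return(sprintf("geometry %d 'is not a LayerGeometry", L))
    if (ncol(lay@weights) != geo@patchLength)
      msg <- c(msg, sprintf("layer %d: weights have %d columns but geometry expects patch length %d",
                            L, ncol(lay@weights), geo@patchLength))
  }
  if (length(msg)) msg else TRUE
})

#' Stopping rule for layer-wise training
#'
#' Training of one layer stops once the smoothed absolute derivative of the
#' input-vs-reconstruction difference falls below `threshold`: with
#' per-iteration difference `d_t` (mean absolute pixel difference between
#' the constant input and its min-max normalised reconstruction), the rule
#' tracks an exponential moving average of `|d_t - d_(t-1)|` with weight
#' `emaCoefficient` on the past, and fires when that average drops below
#' `threshold` after `burnIn` iterations.
#'
#' @slot threshold numeric(1); default `1e-4`.
#' @slot emaCoefficient numeric(1) in (0,1); default `0.99`.
#' @slot burnIn integer(1); iterations before stopping may fire (default 50).
#'
#' @aliases StoppingRule
#' @exportClass StoppingRule
setClass("StoppingRule",
  representation(
    threshold = "numeric",
    emaCoefficient = "numeric",
    burnIn = "integer"
  ),
  prototype(threshold = 1e-4, emaCoefficient = 0.99, burnIn = 50L)
)

setValidity("StoppingRule", function(object) {
  msg <- character(0)
  if (!(length(object@threshold) == 1L && object@threshold > 0))
    msg <- c(msg, "threshold must be a single positive number")
  if (!(length(object@emaCoefficient) == 1L &&
        object@emaCoefficient > 0 && object@emaCoefficient < 1))
    msg <- c(msg, "emaCoefficient must lie in (0, 1)")
  if (!(length(object@burnIn) == 1L && object@burnIn >= 0L))
    msg <- c(msg, "burnIn must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' A pair of bottom-up training streams
#'
#' The training regime feeds two bottom-up streams: a variable stream that
#' yields a fresh image every iteration, and one constant target image whose
#' reconstruction is monitored throughout training. Both are pure functions
#' of the generating seed, so a stream pair replays identically.
#'
#' @slot variable a function of the iteration number returning an image
#'   matrix in `[0, 1]`.
#' @slot constant the constant target image matrix.
#' @slot spec list; the generating specification (kind, size, seed,
#'   parameters), kept for provenance and checkpointing.
#'
#' @seealso [streamPair()]
#' @aliases StreamPair
#' @exportClass StreamPair
setClass("StreamPair",
  representation(
    variable = "function",
    constant = "matrix",
    spec = "list"
  )
)

#' Result of a layer-wise training run
#'
#' Returned by [trainLayerwise()]. Carries the trained stack, the sampled
#' cosine-similarity trace, the per-iteration stopping-metric trace, the
#' per-layer outcomes (`"converged"` or `"max_iterations"`), and any
#' reconstruction snapshots that were requested.
#'
#' @slot stack the trained [MRStack-class].
#' @slot trace data.frame with columns `iteration`, `layer`, `similarity`.
#' @slot metrics data.frame with columns `iteration`, `layer`, `difference`,
#'   `smoothed` (smoothed |derivative| of the difference).
#' @slot outcomes character; one entry per layer.
#' @slot iterations integer; total iterations run per layer.
#' @slot snapshots named list of reconstruction images keyed by iteration.
#' @slot seed integer(1) or NA; the seed the run was started from.
#'
#' @aliases MRTraining
#' @exportClass MRTraining
setClass("MRTraining",
  representation(
    stack = "MRStack",
    trace = "data.frame",
    metrics = "data.frame",
    outcomes = "character",
    iterations = "integer",
    snapshots = "list",
    seed = "integer"
  )
)
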