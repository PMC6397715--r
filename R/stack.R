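buildGeometry <- function(inputDim, cellBlock, windowCells, cellStep, pixelCoverage) {
  inputDim <- as.integer(inputDim); cellBlock <- as.integer(cellBlock)
  windowCells <- as.integer(windowCells); cellStep <- as.integer(cellStep)
  lowerCells <- inputDim %/% cellBlock
  span <- (windowCells - 1L) * cellStep + 1L
  gridDim <- lowerCells - span + 1L
  if (any(gridDim < 1L))
    stop(sprintf("window span (%d x %d cells) exceeds the %d x %d lower grid",
                 span[1L], span[2L], lowerCells[1L], lowerCells[2L]))
  i <- prod(windowCells) * prod(cellBlock)

  # element offsets within one window, patch order row-major over
  # (cell-row, cell-col, within-row, within-col)
  a <- rep(seq_len(windowCells[1L]) - 1L, each = windowCells[2L] * prod(cellBlock))
  b <- rep(rep(seq_len(windowCells[2L]) - 1L, each = prod(cellBlock)),
           times = windowCells[1L])
  u <- rep(rep(seq_len(cellBlock[1L]) - 1L, each = cellBlock[2L]),
           times = prod(windowCells))
  v <- rep(seq_len(cellBlock[2L]) - 1L, times = prod(windowCells) * cellBlock[1L])
  row0 <- a * cellStep[1L] * cellBlock[1L] + u
  col0 <- b * cellStep[2L] * cellBlock[2L] + v
  base <- col0 * inputDim[1L] + row0 + 1L

  # window translations, row-major over window positions
  wr <- rep(seq_len(gridDim[1L]) - 1L, each = gridDim[2L])
  wc <- rep(seq_len(gridDim[2L]) - 1L, times = gridDim[1L])
  shift <- wc * cellBlock[2L] * inputDim[1L] + wr * cellBlock[1L]

  idx <- outer(shift, base, `+`)
  storage.mode(idx) <- "integer"

  new("LayerGeometry",
      gridDim = gridDim, cellBlock = cellBlock, windowCells = windowCells,
      cellStep = cellStep, patchLength = as.integer(i), inputDim = inputDim,
      pixelCoverage = as.integer(pixelCoverage), indexMap = idx)
}

#' Derive the geometry of every layer of a stack configuration
#'
#' Layer 1 slides contiguous windows of `receptiveField` pixels over the
#' image with stride 1. Each higher layer slides (stride 1, in lower-cell
#' units) windows that gather `receptiveField` cell-blocks from the lower
#' layer's packed output grid, with `dilationGap` cells skipped between
#' consecutive gathered cells. A cell-block is the lower bank shape, so a
#' gap of `g` cells corresponds to `g * j_r x g * j_c` skipped output
#' elements. Nominal pixel coverage composes multiplicatively
#' (e.g. 3, 9, 18, 36 for the default four-layer configuration).
#'
#' @param inputSize integer(2); image size in pixels.
#' @param receptiveFields list of integer(2); window extents per layer.
#' @param bankShapes list of integer(2); bank shapes per layer.
#' @param dilationGaps list of integer(2); per-layer gaps (layer 1 is
#'   ignored and treated as contiguous).
#' @return list of [LayerGeometry-class], one per layer.
#' @examples
#' g <- deriveGeometry(c(36, 36),
#'   receptiveFields = list(c(3, 3), c(3, 3), c(2, 2), c(2, 2)),
#'   bankShapes = list(c(3, 12), c(10, 20), c(12, 24), c(8, 16)),
#'   dilationGaps = list(c(0, 0), c(2, 2), c(5, 5), c(11, 11)))
#' vapply(g, function(x) x@gridDim[1], integer(1))   # 34 28 22 10
#' @export
deriveGeometry <- function(inputSize, receptiveFields, bankShapes, dilationGaps) {
  nL <- length(receptiveFields)
  stopifnot(length(bankShapes) == nL, length(dilationGaps) == nL)
  geometry <- vector("list", nL)
  inputDim <- as.integer(inputSize)
  cellBlock <- c(1L, 1L)
  coverage <- 1L
  for (L in seq_len(nL)) {
    step <- if (L == 1L) c(1L, 1L) else as.integer(dilationGaps[[L]]) + 1L
    coverage <- if (L == 1L) as.integer(receptiveFields[[L]][1L])
                else coverage * as.integer(receptiveFields[[L]][1L])
    geometry[[L]] <- tryCatch(
      buildGeometry(inputDim, cellBlock, receptiveFields[[L]], step, coverage),
      error = function(e) stop(sprintf("layer %d: %s", L, conditionMessage(e)),
                               call. = FALSE))
    cellBlock <- as.integer(bankShapes[[L]])
    inputDim <- geometry[[L]]@gridDim * cellBlock
  }
  geometry
}

#' Construct a multi-resolution network stack
#'
#' Defaults reproduce the reference four-layer configuration: a 36 x 36
#' input; receptive fields (3,3), (3,3), (2,2), (2,2); filter banks 3 x 12,
#' 10 x 20, 12 x 24, 8 x 16; learning rate 5e-4 everywhere; dilation gaps
#' 2, 5, 11 for layers 2-4, which yield cell-grid sides 34, 28, 22, 10 and
#' packed output grids 102 x 408, 280 x 560, 264 x 528, 80 x 160.
#'
#' Weights are initialised uniformly in `[-initRange, initRange]` from a
#' seeded generator: a small symmetric start keeps early activations and
#' inhibition buffers small and runs reproducible.
#'
#' @param inputSize integer(2); input image size in pixels.
#' @param receptiveFields list of integer(2) window extents.
#' @param bankShapes list of integer(2) bank shapes.
#' @param dilationGaps list of integer(2) dilation gaps (layer 1 ignored).
#' @param learningRates numeric; per-layer step sizes (recycled). `NA`
#'   requests an automatic input-energy-scaled rate at training time.
#' @param topology inhibition topology, `"printed"` (default) or
#'   `"strict_raster"`; see [inhibitionMask()].
#' @param seed integer seed for weight initialisation (NULL uses the
#'   current RNG state).
#' @param initRange half-width of the uniform initialisation interval.
#' @return an [MRStack-class].
#' @examples
#' st <- MRStack(seed = 1)
#' st
#' @export
MRStack <- function(inputSize = c(36L, 36L),
                    receptiveFields = list(c(3L, 3L), c(3L, 3L), c(2L, 2L), c(2L, 2L)),
                    bankShapes = list(c(3L, 12L), c(10L, 20L), c(12L, 24L), c(8L, 16L)),
                    dilationGaps = list(c(0L, 0L), c(2L, 2L), c(5L, 5L), c(11L, 11L)),
                    learningRates = 5e-4,
                    topology = c("printed", "strict_raster"),
                    seed = NULL,
                    initRange = 0.01) {
  topology <- match.arg(topology)
  nL <- length(receptiveFields)
  stopifnot(length(bankShapes) == nL, length(dilationGaps) == nL, nL >= 1L)
  learningRates <- rep_len(learningRates, nL)
  geometry <- deriveGeometry(inputSize, receptiveFields, bankShapes, dilationGaps)
  layers <- withSeed(seed, lapply(seq_len(nL), function(L) {
    j <- prod(as.integer(bankShapes[[L]]))
    i <- geometry[[L]]@patchLength
    new("MRLayer",
        weights = matrix(stats::runif(j * i, -initRange, initRange), j, i),
        receptiveField = as.integer(receptiveFields[[L]]),
        bankShape = as.integer(bankShapes[[L]]),
        dilationGap = if (L == 1L) c(0L, 0L) else as.integer(dilationGaps[[L]]),
        learningRate = as.numeric(learningRates[[L]]),
        topology = topology, frozen = FALSE)
  }))
  new("MRStack", inputSize = as.integer(inputSize), layers = layers,
      geometry = geometry)
}

packIndex <- function(geometry, bankShape) {
  nr <- geometry@gridDim[1L]; nc <- geometry@gridDim[2L]
  jr <- bankShape[1L]; jc <- bankShape[2L]
  outRows <- nr * jr
  p <- seq_len(nr * nc) - 1L
  r <- p %/% nc; cc <- p %% nc
  shiftP <- cc * jc * outRows + r * jr
  k <- seq_len(jr * jc) - 1L
  fr <- k %/% jc; fc <- k %% jc
  baseK <- fc * outRows + fr + 1L
  idx <- outer(shiftP, baseK, `+`)
  storage.mode(idx) <- "integer"
  idx
}

#' Pack an activation matrix into the 2-D output grid
#'
#' The layer output interleaves the cell grid with the bank layout: the
#' activation of kernel `(f_r, f_c)` at cell `(r, c)` (all 0-based) is
#' stored at output position `(r * j_r + f_r, c * j_c + f_c)`, giving a
#' `(n_r j_r) x (n_c j_c)` matrix — e.g. 102 x 408 for the default layer 1.
#' The placement is bijective; [unpackOutput()] inverts it exactly.
#'
#' @param activation numeric matrix `n x j`.
#' @param geometry the layer's [LayerGeometry-class].
#' @param bankShape integer(2); the layer's bank shape.
#' @return the packed output grid.
#' @export
packOutput <- function(activation, geometry, bankShape) {
  stopifnot(is(geometry, "LayerGeometry"))
  bankShape <- as.integer(bankShape)
  n <- prod(geometry@gridDim); j <- prod(bankShape)
  if (!is.matrix(activation) || !all(dim(activation) == c(n, j)))
    stop(sprintf("activation must be %d x %d for this geometry and bank", n, j))
  idx <- packIndex(geometry, bankShape)
  out <- matrix(0, geometry@gridDim[1L] * bankShape[1L],
                geometry@gridDim[2L] * bankShape[2L])
  out[idx] <- activation
  out
}

#' @rdname packOutput
#' @param grid a packed output grid as produced by [packOutput()].
#' @export
unpackOutput <- function(grid, geometry, bankShape) {
  stopifnot(is(geometry, "LayerGeometry"))
  bankShape <- as.integer(bankShape)
  want <- geometry@gridDim * bankShape
  if (!is.matrix(grid) || !all(dim(grid) == want))
    stop(sprintf("grid must be %d x %d for this geometry and bank",
                 want[1L], want[2L]))
  idx <- packIndex(geometry, bankShape)
  a <- grid[idx]
  dim(a) <- dim(idx)
  a
}

#' Bottom-up forward pass through a stack
#'
#' For each input stream independently: gather patches ([im2row()]),
#' activate ([forwardActivation()]), pack ([packOutput()]), and feed the
#' packed grid to the next layer.
#'
#' @param stack an [MRStack-class].
#' @param images a single image matrix or a list of image matrices (one per
#'   bottom-up stream), each sized `inputSize`.
#' @return for a single image, a list with elements `patches`,
#'   `activations` and `output` (per-layer lists); for a list of images, a
#'   list of such results, one per stream.
#' @export
forwardPass <- function(stack, images) {
  stopifnot(is(stack, "MRStack"))
  single <- is.matrix(images)
  if (single) images <- list(images)
  res <- lapply(images, function(img) {
    if (!is.matrix(img) || !all(dim(img) == stack@inputSize))
      stop(sprintf("each input image must be %d x %d",
                   stack@inputSize[1L], stack@inputSize[2L]))
    nL <- length(stack@layers)
    patches <- activations <- output <- vector("list", nL)
    grid <- img
    for (L in seq_len(nL)) {
      patches[[L]] <- im2row(grid, stack@geometry[[L]])
      activations[[L]] <- forwardActivation(patches[[L]], stack@layers[[L]]@weights)
      output[[L]] <- packOutput(activations[[L]], stack@geometry[[L]],
                                stack@layers[[L]]@bankShape)
      grid <- output[[L]]
    }
    list(patches = patches, activations = activations, output = output)
  })
  if (single) res[[1L]] else res
}

#' Cascaded top-down reconstruction
#'
#' Starting from an activation in layer `fromLayer`'s activation space (or
#' its packed output-grid form), repeatedly synthesises patch rows
#' ([topDownPatches()]), scatters them onto the lower grid with overlap
#' summation ([row2im()]), and treats the result as the lower layer's
#' top-down activation, until an image emerges below layer 1. The whole map
#' is linear. By default overlap sums are kept raw and the layer-1 overlap
#' counts are returned for optional normalisation; with
#' `normalize = TRUE` every stage's scatter is divided by its overlap
#' counts (overlap averaging), which removes the periodic multiplicative
#' envelope the dilated scatter otherwise imprints on intermediate
#' activations and markedly improves multi-layer reconstruction quality.
#'
#' @param stack an [MRStack-class].
#' @param activation numeric matrix: either `n x j` activations of layer
#'   `fromLayer` or that layer's packed output grid.
#' @param fromLayer layer index to start from (default: the top layer).
#' @param normalize divide each stage's overlap sum by its overlap counts
#'   (default `FALSE`: raw sums).
#' @return list with `image` (the reconstructed input-sized matrix) and
#'   `counts` (layer-1 overlap counts).
#' @export
reconstruct <- function(stack, activation, fromLayer = length(stack@layers),
                        normalize = FALSE) {
  stopifnot(is(stack, "MRStack"))
  if (fromLayer < 1L || fromLayer > length(stack@layers))
    stop("fromLayer out of range")
  act <- activation
  for (L in seq(fromLayer, 1L)) {
    geo <- stack@geometry[[L]]
    lay <- stack@layers[[L]]
    n <- prod(geo@gridDim); j <- prod(lay@bankShape)
    if (is.matrix(act) && all(dim(act) == geo@gridDim * lay@bankShape) && !all(dim(act) == c(n, j)))
      act <- unpackOutput(act, geo, lay@bankShape)
    if (!is.matrix(act) || !all(dim(act) == c(n, j)))
      stop(sprintf("layer %d: top-down activation must be %d x %d (or its packed %d x %d form)",
                   L, n, j, geo@gridDim[1L] * lay@bankShape[1L],
                   geo@gridDim[2L] * lay@bankShape[2L]))
    td <- topDownPatches(act, lay@weights)
    scat <- row2im(td, geo)
    act <- if (normalize) scat$grid / pmax(scat$counts, 1L) else scat$grid
  }
  list(image = act, counts = scat$counts)
}

#' Regenerate the receptive-field image of one kernel
#'
#' Places a unit one-hot activation on kernel `kernel` at the top-left
#' window position of layer `layer` and cascades it down with
#' [reconstruct()]; the nominal-coverage-sized patch at the image's
#' top-left corner is returned. For layer 1 this is exactly the kernel
#' reshaped to its window.
#'
#' @param stack an [MRStack-class].
#' @param layer layer index.
#' @param kernel kernel index (1-based, row-major over the bank).
#' @return numeric matrix of side `pixelCoverage` of the layer.
#' @export
visualizeFilter <- function(stack, layer, kernel) {
  stopifnot(is(stack, "MRStack"))
  if (layer < 1L || layer > length(stack@layers)) stop("layer index out of range")
  lay <- stack@layers[[layer]]
  geo <- stack@geometry[[layer]]
  j <- prod(lay@bankShape)
  if (kernel < 1L || kernel > j) stop("kernel index out of range")
  act <- matrix(0, prod(geo@gridDim), j)
  act[1L, kernel] <- 1
  img <- reconstruct(stack, act, fromLayer = layer)$image
  cov <- geo@pixelCoverage
  img[seq_len(cov), seq_len(cov), drop = FALSE]
}
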