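#' Cumulative inhibition mask
#'
#' Builds the binary `j x j` inhibition topology of one filter bank, where
#' `j = prod(bankShape)` and entry `(a, b) = 1` means kernel `a` inhibits
#' kernel `b`. Kernels are indexed row-major over the bank. Two variants:
#'
#' * `"printed"` (default): kernel `a` inhibits `b` iff `bankRow(a) <=
#'   bankRow(b)`. All kernels of a bank row share one inhibition level, and
#'   the set of inhibitors grows (cumulates) row by row — the mechanism that
#'   grades the bank from coarse to fine.
#' * `"strict_raster"`: `a` inhibits `b` iff `a <= b` in row-major kernel
#'   order, i.e. inhibition accumulates kernel by kernel. With a
#'   single-column bank the two variants coincide and the weight update
#'   reduces to Sanger's generalised Hebbian rule.
#'
#' Both variants are reflexive (every kernel inhibits itself), which is what
#' makes the self-term of the update Oja-like.
#'
#' @param bankShape integer(2): bank rows and columns `(j_r, j_c)`.
#' @param topology `"printed"` or `"strict_raster"`.
#' @return binary matrix `j x j`.
#' @examples
#' inhibitionMask(c(2, 1))            # [[1,1],[0,1]]
#' inhibitionMask(c(2, 2))
#' @export
inhibitionMask <- function(bankShape, topology = c("printed", "strict_raster")) {
  topology <- match.arg(topology)
  bankShape <- as.integer(bankShape)
  if (length(bankShape) != 2L || any(is.na(bankShape)) || any(bankShape < 1L))
    stop("'bankShape' must be two positive integers")
  j <- prod(bankShape)
  k <- seq_len(j) - 1L
  if (topology == "printed") {
    row <- k %/% bankShape[2L]
    mask <- outer(row, row, `<=`)
  } else {
    mask <- outer(k, k, `<=`)
  }
  storage.mode(mask) <- "double"
  mask
}

#' Gather sliding-window patches into rows
#'
#' The row-based `im2col` analogue: every (possibly dilated) window of
#' `grid` becomes one row of the returned patch matrix, in row-major window
#' order, with elements flattened row-major over (cell-row, cell-col,
#' within-cell-row, within-cell-col). The gather pattern is fully described
#' by `geometry` (see [deriveGeometry()]).
#'
#' @param grid numeric matrix; the image (layer 1) or the lower layer's
#'   packed output grid.
#' @param geometry a [LayerGeometry-class].
#' @return numeric matrix `n x i` of patches.
#' @seealso [row2im()] for the overlap-summing inverse.
#' @export
im2row <- function(grid, geometry) {
  stopifnot(is(geometry, "LayerGeometry"))
  if (!is.matrix(grid) || !all(dim(grid) == geometry@inputDim))
    stop(sprintf("grid must be a %d x %d matrix for this geometry",
                 geometry@inputDim[1L], geometry@inputDim[2L]))
  patches <- grid[geometry@indexMap]
  dim(patches) <- dim(geometry@indexMap)
  patches
}

#' Scatter patch rows back onto a grid by overlap summation
#'
#' The adjoint of [im2row()]: each patch element is added back to the grid
#' position it was gathered from, so overlapping windows sum. The per-pixel
#' overlap count is returned alongside, so callers can normalise (the raw
#' sum is kept because the regeneration cascade is defined on it).
#'
#' @param rows numeric matrix `n x i` of patch rows.
#' @param geometry a [LayerGeometry-class].
#' @return list with `grid` (overlap sum) and `counts` (integer overlap
#'   counts), both shaped like the geometry's input grid.
#' @export
row2im <- function(rows, geometry) {
  stopifnot(is(geometry, "LayerGeometry"))
  idx <- geometry@indexMap
  if (!is.matrix(rows) || !all(dim(rows) == dim(idx)))
    stop(sprintf("rows must be a %d x %d matrix for this geometry",
                 nrow(idx), ncol(idx)))
  grid <- matrix(0, geometry@inputDim[1L], geometry@inputDim[2L])
  counts <- matrix(0L, geometry@inputDim[1L], geometry@inputDim[2L])
  # within one patch-element column, distinct windows hit distinct pixels,
  # so a plain indexed add per column is a safe scatter
  for (k in seq_len(ncol(idx))) {
    ix <- idx[, k]
    grid[ix] <- grid[ix] + rows[, k]
    counts[ix] <- counts[ix] + 1L
  }
  list(grid = grid, counts = counts)
}

#' Bottom-up activation
#'
#' The purely linear forward map of one layer: `A = I W^T`, the dot product
#' of every patch with every kernel. No nonlinearity, no bias.
#'
#' @param patches numeric matrix `n x i` (one receptive-field patch per row).
#' @param weights numeric matrix `j x i`; the filter bank.
#' @return activation matrix `n x j`.
#' @export
forwardActivation <- function(patches, weights) {
  if (!is.matrix(patches) || !is.matrix(weights) || ncol(patches) != ncol(weights))
    stop("patch length and kernel length disagree")
  patches %*% t(weights)
}

#' Top-down patch synthesis
#'
#' The reverse linear map: `TD = I_TD W`, a per-row linear combination of
#' kernels. A one-hot activation with unit magnitude at kernel `k` returns
#' kernel `w_k` exactly — the primitive behind filter imaging, where each
#' filter is activated in turn and its receptive field regenerated.
#'
#' @param activation numeric matrix `n x j` of top-down activations.
#' @param weights numeric matrix `j x i`; the filter bank.
#' @return patch-row matrix `n x i`.
#' @export
topDownPatches <- function(activation, weights) {
  if (!is.matrix(activation) || !is.matrix(weights) || ncol(activation) != nrow(weights))
    stop("activation width and number of kernels disagree")
  activation %*% weights
}

#' Inhibition buffer
#'
#' For every patch `p` and target kernel `t`, the masked reconstruction of
#' patch `p` from the kernels that inhibit `t`:
#' `buffer(p, t) = sum_s mask[s, t] * activation[p, s] * weights[s, ]`.
#' Stored as an `n x (j*i)` matrix whose column block
#' `((t-1)*i + 1):(t*i)` is slice `t`. This is the quantity subtracted from
#' the input inside the weight update; materialising it is only needed for
#' inspection and testing ([weightDelta()] uses an algebraically collapsed
#' form and never builds it).
#'
#' @param activation numeric matrix `n x j`.
#' @param weights numeric matrix `j x i`.
#' @param mask binary matrix `j x j` from [inhibitionMask()].
#' @return numeric matrix `n x (j*i)`.
#' @export
inhibitionBuffer <- function(activation, weights, mask) {
  j <- nrow(weights)
  if (!is.matrix(activation) || ncol(activation) != j)
    stop("activation width and number of kernels disagree")
  if (!is.matrix(mask) || !all(dim(mask) == c(j, j)))
    stop("mask must be j x j")
  n <- nrow(activation)
  i <- ncol(weights)
  buffer <- matrix(0, n, j * i)
  for (t in seq_len(j)) {
    buffer[, ((t - 1L) * i + 1L):(t * i)] <- activation %*% (mask[, t] * weights)
  }
  buffer
}

#' Cumulative-inhibition weight delta
#'
#' The anti-Hebbian update of one layer. In loop form,
#' `delta[t, ] = alpha * sum_p activation[p, t] *
#'   (patches[p, ] - buffer(p, t))`
#' with `buffer` the inhibition buffer: each kernel moves toward the part of
#' the input its inhibitors fail to account for, weighted by its own
#' activation. The implementation collapses the tiled tensor computation to
#'
#' `delta = alpha * (A^T I - (A^T A * M^T) W)`
#'
#' (with `*` element-wise), which is algebraically identical and never
#' materialises the `n x (j*i)` buffer. With a strict raster mask and a
#' single-column bank the expression is exactly Sanger's generalised
#' Hebbian (deflation) rule.
#'
#' @param patches numeric matrix `n x i`.
#' @param activation numeric matrix `n x j` (normally
#'   `forwardActivation(patches, weights)`).
#' @param weights numeric matrix `j x i`.
#' @param mask binary matrix `j x j`.
#' @param alpha numeric(1); learning rate, >= 0.
#' @return numeric matrix `j x i`; the weight delta.
#' @export
weightDelta <- function(patches, activation, weights, mask, alpha) {
  j <- nrow(weights)
  if (!is.matrix(patches) || ncol(patches) != ncol(weights))
    stop("patch length and kernel length disagree")
  if (!is.matrix(activation) || nrow(activation) != nrow(patches) || ncol(activation) != j)
    stop("activation shape disagrees with patches/weights")
  if (!is.matrix(mask) || !all(dim(mask) == c(j, j)))
    stop("mask must be j x j")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("alpha must be a single finite number")
  alpha * (crossprod(activation, patches) -
             (crossprod(activation) * t(mask)) %*% weights)
}

#' Apply a weight delta
#'
#' Plain element-wise addition `W + delta`; the learning scheme is linear,
#' with no renormalisation and no clipping by default. An optional magnitude
#' clip is available as a divergence guard; it is off by default.
#'
#' @param weights numeric matrix `j x i`.
#' @param delta numeric matrix `j x i`.
#' @param clip optional positive number; if given, entries of the result are
#'   clamped to `[-clip, clip]`.
#' @return the updated weight matrix.
#' @export
applyUpdate <- function(weights, delta, clip = NULL) {
  if (!is.matrix(weights) || !is.matrix(delta) || !all(dim(weights) == dim(delta)))
    stop("weights and delta must be matrices of identical shape")
  out <- weights + delta
  if (!is.null(clip)) {
    stopifnot(is.numeric(clip), length(clip) == 1L, clip > 0)
    out <- pmin(pmax(out, -clip), clip)
  }
  if (!all(is.finite(out)))
    stop(sprintf("non-finite weights after update (max |delta| = %g); ",
                 max(abs(delta))),
         "the learning rate is likely too large for the input scale")
  out
}
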