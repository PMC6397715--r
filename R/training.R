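#' Stopping rule constructor
#'
#' @param threshold stop once the smoothed |derivative| of the
#'   reconstruction difference falls below this (default `1e-4`).
#' @param emaCoefficient exponential-smoothing weight on the past, in
#'   (0, 1); default 0.99, which averages over a few hundred iterations.
#' @param burnIn iterations before the rule may fire (the derivative is
#'   trivially small right after initialisation); default 50.
#' @return a [StoppingRule-class].
#' @export
StoppingRule <- function(threshold = 1e-4, emaCoefficient = 0.99, burnIn = 50L) {
  new("StoppingRule", threshold = as.numeric(threshold),
      emaCoefficient = as.numeric(emaCoefficient), burnIn = as.integer(burnIn))
}

#' One step of the smoothed-derivative stopping metric
#'
#' The per-iteration difference is `d_t = mean(|input - reconstruction|)`
#' with the reconstruction min-max normalised to `[0, 1]`. The rule smooths
#' the absolute derivative `|d_t - d_(t-1)|` with an exponential moving
#' average and fires once the smoothed value drops below the threshold
#' after the burn-in. The first iteration has no derivative and never
#' stops.
#'
#' @param input the target image.
#' @param reconstruction the raw reconstructed image (same shape).
#' @param state list carried between calls: `iter`, `prevDiff`, `smoothed`.
#'   Pass `NULL` (or an empty list) to initialise.
#' @param rule a [StoppingRule-class].
#' @return list with the updated `state` (including `difference`), and
#'   `stop` (logical).
#' @export
stoppingStep <- function(input, reconstruction, state, rule = StoppingRule()) {
  if (!all(dim(input) == dim(reconstruction)))
    stop("input and reconstruction must have identical shape")
  if (is.null(state) || length(state) == 0L)
    state <- list(iter = 0L, prevDiff = NA_real_, smoothed = NA_real_)
  d <- mean(abs(input - minMax(reconstruction)))
  state$iter <- state$iter + 1L
  if (is.na(state$prevDiff)) {
    stop_now <- FALSE
  } else {
    deriv <- abs(d - state$prevDiff)
    state$smoothed <- if (is.na(state$smoothed)) deriv
      else rule@emaCoefficient * state$smoothed + (1 - rule@emaCoefficient) * deriv
    stop_now <- state$iter > rule@burnIn && state$smoothed < rule@threshold
  }
  state$prevDiff <- d
  state$difference <- d
  list(state = state, stop = stop_now)
}

#' Cosine similarity between an image and its reconstruction
#'
#' Both images are cropped by `cropMargin` pixels on every side (removing
#' the darkened-frame artifact of overlap-summed regeneration), min-max
#' normalised to `[0, 1]`, optionally mean-centred, flattened, and compared
#' by the cosine of their angle. If either vector has zero norm after
#' normalisation the similarity is defined as 0, with a warning.
#'
#' @param input,reconstruction image matrices of identical shape.
#' @param cropMargin pixels to trim on each side (default 2, one less than
#'   the default layer-1 field size).
#' @param normalization `"minmax"` (plain cosine of the normalised images)
#'   or `"centered"` (means removed after min-max normalisation, making the
#'   measure invariant to a shared intensity offset).
#' @return a number in `[-1, 1]`.
#' @export
cosineSimilarity <- function(input, reconstruction, cropMargin = 2L,
                             normalization = c("minmax", "centered")) {
  normalization <- match.arg(normalization)
  if (!all(dim(input) == dim(reconstruction)))
    stop("images must have identical shape")
  m <- as.integer(cropMargin)
  d <- dim(input)
  if (2L * m >= min(d)) stop("cropMargin leaves no pixels")
  rows <- (1L + m):(d[1L] - m); cols <- (1L + m):(d[2L] - m)
  a <- minMax(input[rows, cols]); b <- minMax(reconstruction[rows, cols])
  if (normalization == "centered") {
    a <- a - mean(a); b <- b - mean(b)
  }
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("zero-norm image after normalization; similarity defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Automatic learning rate from input energy
#'
#' `alpha = scale / sum(patches^2)`. The total patch energy of one
#' iteration bounds the largest eigenvalue of the per-iteration Gram
#' matrix, so `alpha * lambda_max <= scale` and the linear learning
#' dynamics stay contractive; the default `scale = 0.5` leaves a factor-2
#' safety margin, which matters at higher layers whose patch covariance is
#' nearly rank-one (`lambda_max` close to the full energy). When training
#' with several streams, pass the patches of all streams of one iteration.
#' At a 36 x 36 input in `[0, 1]` the rule lands within a small factor of
#' the reference rate 5e-4 for layer 1, and scales automatically to higher
#' layers whose patch energy is orders of magnitude larger.
#'
#' @param patches one iteration's patch matrix (rows from all streams).
#' @param scale dimensionless safety factor in (0, 1]; default 0.5.
#' @return a learning rate.
#' @export
autoLearningRate <- function(patches, scale = 0.5) {
  e <- sum(patches^2)
  if (e == 0) stop("cannot derive a learning rate from all-zero patches")
  scale / e
}

#' Layer-wise training with cumulative inhibition
#'
#' Trains the stack one layer at a time, starting at layer 1: the current
#' layer learns from every bottom-up stream (the variable stream and the
#' constant target of `streams`) while all other layers stay frozen; each
#' stream's weight delta is applied sequentially within an iteration. The
#' layer trains until the smoothed-derivative stopping rule fires (never
#' before `minIter` iterations for that layer), is then frozen, and
#' training proceeds to the next layer. A layer that exhausts `maxIter`
#' iterations is reported with outcome `"max_iterations"` (with a warning),
#' never silently.
#'
#' Two reconstructions of the constant image are monitored. The stopping
#' metric compares the input with the reconstruction through layers
#' `1..L` only (top-down from the training layer's own activation): only
#' trained layers participate in the layer's own convergence test. The
#' similarity trace instead follows the full-model reconstruction — the
#' top layer's activation cascaded all the way down, untrained upper
#' layers included — which is what the regeneration architecture defines
#' as "the" reconstruction; its cosine similarity
#' ([cosineSimilarity()]) is sampled every `sampleEvery`-th iteration
#' (default 5). Both reconstructions use overlap averaging (see
#' [reconstruct()]). The iteration counter is global across layers, so
#' the similarity trace spans the whole schedule.
#'
#' @param stack an [MRStack-class].
#' @param streams a [StreamPair-class].
#' @param rule a [StoppingRule-class].
#' @param minIter,maxIter per-layer bounds on training iterations.
#' @param seed integer; seeds all randomness of the run.
#' @param sampleEvery cadence of similarity sampling (default every 5th
#'   iteration).
#' @param snapshotAt integer vector of global iterations at which to store
#'   the reconstruction image of the constant stream.
#' @param similarityNormalization normalization mode of the trace, see
#'   [cosineSimilarity()]; the trace defaults to `"centered"` because the
#'   raw overlap-summed reconstruction carries an arbitrary intensity
#'   offset.
#' @param clip optional magnitude clip forwarded to [applyUpdate()].
#' @param verbose print per-layer progress.
#' @return an [MRTraining-class].
#' @export
trainLayerwise <- function(stack, streams, rule = StoppingRule(),
                           minIter = 0L, maxIter = 500000L, seed = NULL,
                           sampleEvery = 5L, snapshotAt = integer(0),
                           similarityNormalization = "centered",
                           clip = NULL, verbose = FALSE) {
  stopifnot(is(stack, "MRStack"), is(streams, "StreamPair"), is(rule, "StoppingRule"))
  nL <- length(stack@layers)
  minIter <- rep_len(as.integer(minIter), nL)
  maxIter <- rep_len(as.integer(maxIter), nL)
  constant <- streams@constant
  if (!all(dim(constant) == stack@inputSize))
    stop("constant stream image does not match the stack input size")

  outcomes <- character(nL)
  perLayerIter <- integer(nL)
  traceIter <- traceLayer <- integer(0); traceSim <- numeric(0)
  metIter <- metLayer <- integer(0); metDiff <- metSmooth <- numeric(0)
  snapshots <- list()
  globalIter <- 0L

  withSeed(seed, {
    for (L in seq_len(nL)) {
      lay <- stack@layers[[L]]
      geo <- stack@geometry[[L]]
      mask <- inhibitionMask(lay@bankShape, lay@topology)
      # lower layers are frozen while L trains: cache the constant stream's
      # patches at layer L once
      lowerForward <- function(img) {
        grid <- img
        if (L > 1L) for (K in seq_len(L - 1L)) {
          a <- forwardActivation(im2row(grid, stack@geometry[[K]]),
                                 stack@layers[[K]]@weights)
          grid <- packOutput(a, stack@geometry[[K]], stack@layers[[K]]@bankShape)
        }
        im2row(grid, geo)
      }
      patchesC <- lowerForward(constant)
      alpha <- lay@learningRate
      W <- lay@weights
      state <- NULL
      local <- 0L
      outcomes[L] <- "max_iterations"
      repeat {
        if (local >= maxIter[L]) break
        local <- local + 1L; globalIter <- globalIter + 1L
        patchesV <- lowerForward(streams@variable(globalIter))
        if (is.na(alpha)) alpha <- autoLearningRate(rbind(patchesV, patchesC))
        for (patches in list(patchesV, patchesC)) {
          A <- forwardActivation(patches, W)
          W <- applyUpdate(W, weightDelta(patches, A, W, mask, alpha), clip = clip)
        }
        stack@layers[[L]]@weights <- W
        recon <- reconstruct(stack,
                             forwardActivation(patchesC, W),
                             fromLayer = L, normalize = TRUE)$image
        st <- stoppingStep(constant, recon, state, rule)
        state <- st$state
        metIter <- c(metIter, globalIter); metLayer <- c(metLayer, L)
        metDiff <- c(metDiff, state$difference); metSmooth <- c(metSmooth, state$smoothed)
        wantSim <- globalIter %% sampleEvery == 0L
        wantSnap <- globalIter %in% snapshotAt
        if (wantSim || wantSnap) {
          reconFull <- if (L == nL) recon else
            fullReconstruction(stack, constant)
          if (wantSim) {
            traceIter <- c(traceIter, globalIter); traceLayer <- c(traceLayer, L)
            traceSim <- c(traceSim,
                          cosineSimilarity(constant, reconFull,
                                           normalization = similarityNormalization))
          }
          if (wantSnap) snapshots[[as.character(globalIter)]] <- reconFull
        }
        if (st$stop && local >= minIter[L]) { outcomes[L] <- "converged"; break }
      }
      perLayerIter[L] <- local
      lay@weights <- W
      lay@learningRate <- alpha
      lay@frozen <- TRUE
      stack@layers[[L]] <- lay
      if (outcomes[L] == "max_iterations")
        warning(sprintf("layer %d reached the maximum of %d iterations without converging",
                        L, maxIter[L]))
      if (verbose)
        message(sprintf("layer %d: %s after %d iterations (metric %.3g)",
                        L, outcomes[L], local,
                        if (is.na(state$smoothed)) NA else state$smoothed))
    }
  })

  new("MRTraining", stack = stack,
      trace = data.frame(iteration = traceIter, layer = traceLayer,
                         similarity = traceSim),
      metrics = data.frame(iteration = metIter, layer = metLayer,
                           difference = metDiff, smoothed = metSmooth),
      outcomes = outcomes, iterations = perLayerIter, snapshots = snapshots,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# Full-model reconstruction of an image: forward to the top layer, then
# cascade top-down with overlap averaging.
fullReconstruction <- function(stack, image) {
  fp <- forwardPass(stack, image)
  reconstruct(stack, fp$activations[[length(stack@layers)]],
              normalize = TRUE)$image
}

#' Reconstruction snapshots over a training run
#'
#' Runs [trainLayerwise()] while recording the constant stream's
#' reconstruction at the requested global iterations, mirroring the
#' regenerated-image series used to illustrate how detail accrues as the
#' top layer stabilises.
#'
#' @inheritParams trainLayerwise
#' @param iterations global iterations at which to store reconstructions.
#' @param ... forwarded to [trainLayerwise()].
#' @return list with `images` (named list of snapshots) and `training`
#'   (the full [MRTraining-class]).
#' @export
snapshotReconstruction <- function(stack, streams, iterations, ...) {
  tr <- trainLayerwise(stack, streams, snapshotAt = as.integer(iterations), ...)
  list(images = tr@snapshots, training = tr)
}
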