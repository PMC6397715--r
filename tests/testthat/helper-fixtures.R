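# Small stacks and the shared scaled training study used by several tests.

tinyStack <- function(inputSize = c(8, 8),
                      receptiveFields = list(c(3, 3), c(2, 2)),
                      bankShapes = list(c(2, 3), c(2, 2)),
                      dilationGaps = list(c(0, 0), c(1, 1)),
                      seed = 42, ...) {
  MRStack(inputSize = inputSize, receptiveFields = receptiveFields,
          bankShapes = bankShapes, dilationGaps = dilationGaps,
          seed = seed, ...)
}

# The two-layer pink-noise study: a scaled-down version of the reference
# configuration with a strict top-layer rank bottleneck (12 kernels over
# 216-dim patches). Run once per test session and shared by the
# qualitative acceptance checks.
.studyCache <- new.env(parent = emptyenv())

scaledStudy <- function(seed = 1L) {
  key <- as.character(seed)
  if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
  st <- MRStack(inputSize = c(24, 24),
                receptiveFields = list(c(3, 3), c(3, 3)),
                bankShapes = list(c(3, 8), c(6, 2)),
                dilationGaps = list(c(0, 0), c(2, 2)),
                learningRates = c(5e-4, NA),
                seed = seed + 1000L)
  sp <- streamPair("pink_noise", size = c(24, 24), seed = seed)
  layer1Iter <- 800L
  tr <- suppressWarnings(trainLayerwise(
    st, sp, minIter = c(layer1Iter, 6000L), maxIter = c(layer1Iter, 6000L),
    seed = seed, snapshotAt = layer1Iter + 2L))
  res <- list(training = tr, streams = sp, topPhaseStart = layer1Iter + 2L)
  .studyCache[[key]] <- res
  res
}
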