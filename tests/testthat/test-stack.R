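test_that("the default configuration reproduces every printed dimension", {
  st <- MRStack(seed = 1)
  g <- layerGeometry(st)
  expect_equal(vapply(g, function(x) x@gridDim, integer(2)),
               cbind(c(34L, 34L), c(28L, 28L), c(22L, 22L), c(10L, 10L)))
  expect_equal(vapply(g, function(x) x@patchLength, integer(1)),
               c(9L, 324L, 800L, 1152L))
  expect_equal(vapply(g, function(x) x@pixelCoverage, integer(1)),
               c(3L, 9L, 18L, 36L))
  # packed output grids per layer
  outDims <- mapply(function(geo, lay) geo@gridDim * lay@bankShape,
                    g, st@layers)
  expect_equal(outDims, cbind(c(102L, 408L), c(280L, 560L),
                              c(264L, 528L), c(80L, 160L)))
  # layer-2 gathered cell-blocks are separated by 2 cells = 6 x 24 elements
  gap <- (g[[2]]@cellStep - 1L) * g[[2]]@cellBlock
  expect_equal(gap, c(6L, 24L))
})

test_that("geometry derivation handles custom and degenerate setups", {
  # single layer whose window equals the image: a 1 x 1 grid
  g <- deriveGeometry(c(5, 5), list(c(5, 5)), list(c(2, 2)), list(c(0, 0)))
  expect_equal(g[[1]]@gridDim, c(1L, 1L))

  # 8x8 input, 2x2 stride-1 layer 1 (7x7 cells); layer-2 2x2 window with
  # gap 1 spans 3 cells: 7 - 3 + 1 = 5
  g2 <- deriveGeometry(c(8, 8), list(c(2, 2), c(2, 2)),
                       list(c(2, 2), c(2, 2)), list(c(0, 0), c(1, 1)))
  expect_equal(g2[[1]]@gridDim, c(7L, 7L))
  expect_equal(g2[[2]]@gridDim, c(5L, 5L))

  # a window that cannot fit names the offending layer
  expect_error(deriveGeometry(c(6, 6), list(c(3, 3), c(3, 3)),
                              list(c(2, 2), c(2, 2)), list(c(0, 0), c(2, 2))),
               "layer 2")
})

test_that("pack/unpack is the documented bijection", {
  st <- tinyStack()
  g <- layerGeometry(st, 1)
  bank <- bankShape(st, 1)
  n <- prod(g@gridDim); j <- prod(bank)
  A <- matrix(rnorm(n * j), n, j)
  packed <- packOutput(A, g, bank)
  expect_equal(dim(packed), g@gridDim * bank)
  expect_equal(unpackOutput(packed, g, bank), A)

  # explicit placement rule: cell (r, c), kernel (f_r, f_c) lands at
  # (r*j_r + f_r, c*j_c + f_c), all 0-based
  for (trial in 1:20) {
    p <- sample(n, 1); k <- sample(j, 1)
    r <- (p - 1) %/% g@gridDim[2]; cc <- (p - 1) %% g@gridDim[2]
    fr <- (k - 1) %/% bank[2]; fc <- (k - 1) %% bank[2]
    expect_equal(packed[r * bank[1] + fr + 1, cc * bank[2] + fc + 1], A[p, k])
  }

  # 1x1 grid with a 1x1 bank is the scalar identity
  g1 <- deriveGeometry(c(2, 2), list(c(2, 2)), list(c(1, 1)), list(c(0, 0)))[[1]]
  expect_equal(packOutput(matrix(3.5), g1, c(1, 1)), matrix(3.5))

  expect_error(packOutput(matrix(0, 2, 2), g, bank), "activation")
})

test_that("forward pass cascades and handles streams", {
  st <- MRStack(seed = 1)
  img <- pinkNoiseImage(c(36, 36), seed = 9)
  fp <- forwardPass(st, img)
  expect_equal(vapply(fp$output, dim, integer(2)),
               cbind(c(102L, 408L), c(280L, 560L), c(264L, 528L), c(80L, 160L)))

  # zero image: all-zero grids at every layer
  fp0 <- forwardPass(st, matrix(0, 36, 36))
  for (o in fp0$output) expect_true(all(o == 0))

  # two identical streams give identical per-layer outputs
  fp2 <- forwardPass(st, list(img, img))
  expect_identical(fp2[[1]]$output, fp2[[2]]$output)

  expect_error(forwardPass(st, matrix(0, 10, 10)), "36 x 36")
})

test_that("reconstruction cascades down to an input-sized image", {
  st <- MRStack(seed = 1)
  # top activation 100 x 128 (10x10 grid, 8x16 bank) yields a 36 x 36 image
  act <- matrix(rnorm(100 * 128), 100, 128)
  r <- reconstruct(st, act)
  expect_equal(dim(r$image), c(36L, 36L))
  # the packed 80 x 160 form is accepted too and gives the same image
  packed <- packOutput(act, layerGeometry(st, 4), bankShape(st, 4))
  expect_equal(reconstruct(st, packed)$image, r$image)

  expect_equal(reconstruct(st, 0 * act)$image, matrix(0, 36, 36))

  expect_error(reconstruct(st, matrix(0, 3, 3)), "layer 4")
})

test_that("reconstruction is linear in the top activation", {
  st <- tinyStack(seed = 7)
  g <- layerGeometry(st, 2)
  n <- prod(g@gridDim); j <- prod(bankShape(st, 2))
  a1 <- matrix(rnorm(n * j), n, j)
  a2 <- matrix(rnorm(n * j), n, j)
  r12 <- reconstruct(st, 2 * a1 - 0.5 * a2)$image
  expect_equal(r12, 2 * reconstruct(st, a1)$image - 0.5 * reconstruct(st, a2)$image,
               tolerance = 1e-10)
})

test_that("a one-layer identity stack reconstructs its input exactly", {
  st <- MRStack(inputSize = c(4, 4), receptiveFields = list(c(1, 1)),
                bankShapes = list(c(1, 1)), dilationGaps = list(c(0, 0)),
                seed = 1)
  filterWeights(st, 1) <- matrix(1, 1, 1)
  x <- matrix(rnorm(16), 4, 4)
  fp <- forwardPass(st, x)
  expect_equal(reconstruct(st, fp$activations[[1]], fromLayer = 1)$image, x)
})

test_that("filter visualisation regenerates kernels and composes layers", {
  st <- MRStack(seed = 3)
  # layer 1: the filter image is the kernel reshaped to its 3 x 3 window
  w7 <- filterWeights(st, 1)[7, ]
  expect_equal(as.vector(t(visualizeFilter(st, 1, 7))), w7)

  # zero weights regenerate a zero patch
  st0 <- tinyStack()
  filterWeights(st0, 1) <- 0 * filterWeights(st0, 1)
  filterWeights(st0, 2) <- 0 * filterWeights(st0, 2)
  expect_equal(visualizeFilter(st0, 2, 1),
               matrix(0, layerGeometry(st0, 2)@pixelCoverage,
                      layerGeometry(st0, 2)@pixelCoverage))

  # layer-2 filter image equals the two-stage linear expansion done by
  # hand: scatter the kernel into the layer-1 output space, unpack, then
  # overlap-sum the layer-1 synthesis
  st2 <- tinyStack(seed = 12)
  k <- 3
  g2 <- layerGeometry(st2, 2); g1 <- layerGeometry(st2, 1)
  act <- matrix(0, prod(g2@gridDim), prod(bankShape(st2, 2)))
  act[1, k] <- 1
  td <- topDownPatches(act, filterWeights(st2, 2))
  lower <- row2im(td, g2)$grid
  a1 <- unpackOutput(lower, g1, bankShape(st2, 1))
  img <- row2im(topDownPatches(a1, filterWeights(st2, 1)), g1)$grid
  cov <- g2@pixelCoverage
  expect_equal(visualizeFilter(st2, 2, k), img[1:cov, 1:cov])

  expect_error(visualizeFilter(st, 5, 1), "layer")
  expect_error(visualizeFilter(st, 1, 37), "kernel")
})

test_that("overlap-normalised reconstruction averages each stage", {
  st <- tinyStack(seed = 5)
  g2 <- layerGeometry(st, 2)
  n <- prod(g2@gridDim); j <- prod(bankShape(st, 2))
  act <- matrix(rnorm(n * j), n, j)
  raw <- reconstruct(st, act)
  # single-layer case: normalisation just divides by the final counts
  a1 <- matrix(rnorm(prod(layerGeometry(st, 1)@gridDim) * 6), ncol = 6)
  r1raw <- reconstruct(st, a1, fromLayer = 1)
  r1n <- reconstruct(st, a1, fromLayer = 1, normalize = TRUE)
  expect_equal(r1n$image, r1raw$image / pmax(r1raw$counts, 1))
  # and it is still linear
  r2n <- reconstruct(st, 3 * act, normalize = TRUE)
  expect_equal(r2n$image, 3 * reconstruct(st, act, normalize = TRUE)$image,
               tolerance = 1e-10)
  expect_equal(dim(raw$image), c(8L, 8L))
})
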