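#' Deterministic per-iteration stream seed
#'
#' Derives the seed used for iteration `k` of a stream generated with base
#' seed `seed`. A fixed linear-congruential mix keeps results inside the
#' 32-bit integer range, so every stream image can be replayed in
#' isolation.
#'
#' @param seed base seed of the stream.
#' @param k iteration number (0 denotes the constant image).
#' @return an integer seed.
#' @export
streamSeed <- function(seed, k) {
  m <- 2147483647
  as.integer((((as.numeric(seed) %% m) * 69069) %% m + (as.numeric(k) * 2147483) %% m + 101) %% m)
}

radialFrequency <- function(nr, nc) {
  fy <- c(0:(nr %/% 2), -(((nr - 1) %/% 2):1)) / nr
  fx <- c(0:(nc %/% 2), -(((nc - 1) %/% 2):1)) / nc
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Pink-noise image
#'
#' Synthesises a natural-image-like texture in the frequency domain:
#' Gaussian white noise is transformed, its amplitude is shaped by
#' `f^(-beta/2)` (so power falls as `f^-beta`, i.e. the radially averaged
#' log power is near log-linear across spatial frequencies), the DC
#' component is zeroed, and the inverse transform is min-max mapped to
#' `[0, 1]`. `beta = 2` approximates natural-image statistics.
#'
#' @param size integer(2) image size (default 36 x 36).
#' @param beta spectral exponent, > 0.
#' @param seed integer seed; the image is a pure function of
#'   `(size, beta, seed)`.
#' @return matrix in `[0, 1]`.
#' @export
pinkNoiseImage <- function(size = c(36L, 36L), beta = 2, seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 2L)) stop("degenerate image size")
  if (beta <= 0) stop("beta must be > 0")
  wn <- withSeed(seed, matrix(stats::rnorm(prod(size)), size[1L], size[2L]))
  f <- radialFrequency(size[1L], size[2L])
  amp <- f
  amp[f > 0] <- f[f > 0]^(-beta / 2)
  amp[1L, 1L] <- 0
  img <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / prod(size)
  minMax(img)
}

#' Sinusoidal grating image
#'
#' `sin(2 pi f (u cos(theta) + v sin(theta)) + phase)` on normalised
#' coordinates, rescaled to `[0, 1]`. `frequency` is in cycles per image;
#' it must stay below the Nyquist limit `min(size)/2`.
#'
#' @param size integer(2) image size.
#' @param frequency cycles per image (0 gives a constant image).
#' @param orientation grating orientation in radians (0: vertical stripes,
#'   rows identical).
#' @param phase phase offset in radians.
#' @return matrix in `[0, 1]`.
#' @export
gratingImage <- function(size = c(36L, 36L), frequency = 4, orientation = 0,
                         phase = 0) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) stop("degenerate image size")
  if (frequency < 0 || frequency >= min(size) / 2)
    stop(sprintf("frequency %g is aliased for a %d x %d image (Nyquist %g)",
                 frequency, size[1L], size[2L], min(size) / 2))
  u <- matrix(rep((seq_len(size[2L]) - 1) / size[2L], each = size[1L]),
              size[1L], size[2L])
  v <- matrix(rep((seq_len(size[1L]) - 1) / size[1L], times = size[2L]),
              size[1L], size[2L])
  s <- sin(2 * pi * frequency * (u * cos(orientation) + v * sin(orientation)) + phase)
  (s + 1) / 2
}

#' Gaussian blob scene
#'
#' Sums seeded isotropic Gaussian blobs with random centres and amplitudes
#' and clips the result to `[0, 1]`. Zero blobs yield a blank image.
#'
#' @param size integer(2) image size.
#' @param nBlobs number of blobs (>= 0).
#' @param width blob standard deviation in pixels.
#' @param seed integer seed.
#' @param centers optional `nBlobs x 2` matrix of (row, col) centres
#'   overriding the random placement (amplitudes become 1).
#' @return matrix in `[0, 1]`.
#' @export
blobScene <- function(size = c(36L, 36L), nBlobs = 6L, width = 3, seed = 1L,
                      centers = NULL) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) stop("degenerate image size")
  if (nBlobs < 0L) stop("nBlobs must be >= 0")
  img <- matrix(0, size[1L], size[2L])
  if (nBlobs == 0L) return(img)
  if (is.null(centers)) {
    par <- withSeed(seed, list(
      r = stats::runif(nBlobs, 1, size[1L]),
      c = stats::runif(nBlobs, 1, size[2L]),
      a = stats::runif(nBlobs, 0.5, 1)))
  } else {
    stopifnot(nrow(centers) == nBlobs)
    par <- list(r = centers[, 1L], c = centers[, 2L], a = rep(1, nBlobs))
  }
  rows <- seq_len(size[1L]); cols <- seq_len(size[2L])
  for (b in seq_len(nBlobs)) {
    g <- exp(-outer((rows - par$r[b])^2, (cols - par$c[b])^2, `+`) / (2 * width^2))
    img <- img + par$a[b] * g
  }
  pmin(img, 1)
}

#' Construct a variable-plus-constant stream pair
#'
#' The training regime pairs a variable bottom-up stream (a fresh image per
#' iteration) with one constant target image. Every image is a pure
#' function of `(kind, size, seed, iteration)`: iteration `k` of the
#' variable stream uses seed `streamSeed(seed, k)` and the constant image
#' uses `streamSeed(seed, 0)`, so runs replay bit-identically.
#'
#' @param kind `"pink_noise"` or `"blobs"`.
#' @param size integer(2) image size.
#' @param seed base seed of the pair.
#' @param beta spectral exponent for pink noise.
#' @param nBlobs,width blob parameters for `kind = "blobs"`.
#' @return a [StreamPair-class].
#' @export
streamPair <- function(kind = c("pink_noise", "blobs"), size = c(36L, 36L),
                       seed = 1L, beta = 2, nBlobs = 6L, width = 3) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  gen <- switch(kind,
    pink_noise = function(s) pinkNoiseImage(size, beta, seed = s),
    blobs = function(s) blobScene(size, nBlobs, width, seed = s))
  new("StreamPair",
      variable = function(k) gen(streamSeed(seed, k)),
      constant = gen(streamSeed(seed, 0L)),
      spec = list(kind = kind, size = size, seed = as.integer(seed),
                  beta = beta, nBlobs = nBlobs, width = width))
}

#' Read a CIFAR-10 binary batch as a grayscale image stream
#'
#' Parses the binary batch layout (per record: one label byte followed by
#' 1024 red, 1024 green and 1024 blue bytes, row-major 32 x 32), converts
#' to luminance (0.299/0.587/0.114) in `[0, 1]`, and adapts each image to
#' `inputSize` either by symmetric zero padding (default, preserves native
#' statistics) or bilinear resizing. The file is never bundled and never
#' required by any test; a missing or truncated file is an explicit error.
#'
#' @param path path to a `data_batch_*.bin` file.
#' @param inputSize integer(2) target size (default 36 x 36).
#' @param method `"pad"` or `"resize"`.
#' @return list with `n` (number of records) and `image(k)`, a function
#'   returning the k-th image.
#' @export
loadCifarStream <- function(path, inputSize = c(36L, 36L),
                            method = c("pad", "resize")) {
  method <- match.arg(method)
  inputSize <- as.integer(inputSize)
  if (!file.exists(path)) stop(sprintf("CIFAR batch file not found: %s", path))
  recordBytes <- 3073L
  sz <- file.size(path)
  if (sz == 0 || sz %% recordBytes != 0)
    stop(sprintf("corrupt CIFAR batch: %d bytes is not a multiple of %d",
                 sz, recordBytes))
  n <- as.integer(sz %/% recordBytes)
  image <- function(k) {
    stopifnot(k >= 1L, k <= n)
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, (k - 1L) * recordBytes + 1L)  # skip the label byte
    raw <- as.integer(readBin(con, "raw", 3072L)) / 255
    chan <- function(o) t(matrix(raw[(o + 1L):(o + 1024L)], 32L, 32L))  # row-major
    g <- 0.299 * chan(0L) + 0.587 * chan(1024L) + 0.114 * chan(2048L)
    adaptImage(g, inputSize, method)
  }
  list(n = n, image = image)
}

adaptImage <- function(img, size, method) {
  d <- dim(img)
  if (all(d == size)) return(img)
  if (method == "pad") {
    out <- matrix(0, size[1L], size[2L])
    off <- pmax((size - d) %/% 2L, 0L)
    take <- pmin(d, size)
    out[off[1L] + seq_len(take[1L]), off[2L] + seq_len(take[2L])] <-
      img[seq_len(take[1L]), seq_len(take[2L])]
    out
  } else {
    # bilinear resize
    sr <- (d[1L] - 1) / max(size[1L] - 1, 1)
    sc <- (d[2L] - 1) / max(size[2L] - 1, 1)
    r <- (seq_len(size[1L]) - 1) * sr + 1
    cc <- (seq_len(size[2L]) - 1) * sc + 1
    r0 <- pmin(floor(r), d[1L] - 1L); c0 <- pmin(floor(cc), d[2L] - 1L)
    fr <- r - r0; fc <- cc - c0
    (1 - fr) %o% (1 - fc) * img[r0, c0, drop = FALSE] +
      fr %o% (1 - fc) * img[r0 + 1L, c0, drop = FALSE] +
      (1 - fr) %o% fc * img[r0, c0 + 1L, drop = FALSE] +
      fr %o% fc * img[r0 + 1L, c0 + 1L, drop = FALSE]
  }
}
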