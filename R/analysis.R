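#' Radially averaged power spectrum of an image
#'
#' Computes the 2-D discrete Fourier power of the image and averages it
#' over annuli of integer radial frequency. Frequencies are in cycles per
#' image (for a regenerated filter image, cycles per receptive field). The
#' `power` column is linear; `powerDb` is `10 log10` with the zero-power
#' floor mapped to the smallest representable level.
#'
#' @param image numeric matrix.
#' @return data.frame with columns `frequency` (strictly increasing),
#'   `power`, `powerDb`, and `count` (bins per annulus, so that
#'   `sum(power * count)` preserves total spectral power).
#' @export
imageSpectrum <- function(image) {
  if (!is.matrix(image) || any(dim(image) < 1L)) stop("non-empty image required")
  P <- Mod(stats::fft(image))^2
  d <- dim(image)
  # signed integer frequency indices per axis, scaled to cycles per image
  # of the shorter side so annuli are isotropic
  ky <- c(0:(d[1L] %/% 2), -(((d[1L] - 1) %/% 2):1)) / d[1L]
  kx <- c(0:(d[2L] %/% 2), -(((d[2L] - 1) %/% 2):1)) / d[2L]
  r <- sqrt(outer(ky^2, kx^2, `+`)) * min(d)
  bin <- round(r)
  agg <- tapply(as.vector(P), as.vector(bin), mean)
  cnt <- tapply(as.vector(P), as.vector(bin), length)
  freq <- as.numeric(names(agg))
  o <- order(freq)
  power <- as.numeric(agg)[o]
  data.frame(frequency = freq[o],
             power = power,
             powerDb = 10 * log10(pmax(power, .Machine$double.xmin)),
             count = as.numeric(cnt)[o])
}

#' Power-weighted mean spatial frequency
#'
#' The spectral centroid of a radially averaged profile; used to order
#' filter-bank rows along the coarse-to-fine axis.
#'
#' @param spectrum a data.frame from [imageSpectrum()] (or any frame with
#'   `frequency` and `power` columns; a `count` column, when present,
#'   weights each annulus by its number of 2-D bins so the centroid is the
#'   power-weighted mean over the full 2-D spectrum).
#' @return a frequency.
#' @export
spectralCentroid <- function(spectrum) {
  p <- spectrum$power
  if (!is.null(spectrum$count)) p <- p * spectrum$count
  if (sum(p) == 0) return(0)
  sum(spectrum$frequency * p) / sum(p)
}

#' Average power spectrum of each filter-bank row
#'
#' Regenerates every kernel's receptive-field image of one layer
#' ([visualizeFilter()]), computes each radially averaged power spectrum,
#' and averages the linear power within each bank row. Power is reported in
#' dB relative to the profile maximum; frequency is in cycles per
#' receptive field. On a trained stack the per-row spectra migrate from
#' low to high frequencies with increasing row index — the coarse-to-fine
#' gradient induced by cumulative inhibition.
#'
#' @param stack an [MRStack-class].
#' @param layer layer index.
#' @return data.frame with columns `row`, `frequency`, `power` (linear,
#'   per-annulus mean), `count` (bins per annulus) and `powerDb` (dB
#'   relative to the profile maximum).
#' @export
rowPowerSpectrum <- function(stack, layer) {
  stopifnot(is(stack, "MRStack"))
  lay <- stack@layers[[layer]]
  jr <- lay@bankShape[1L]; jc <- lay@bankShape[2L]
  rows <- vector("list", jr)
  for (r in seq_len(jr)) {
    acc <- NULL
    for (cc in seq_len(jc)) {
      k <- (r - 1L) * jc + cc
      sp <- imageSpectrum(visualizeFilter(stack, layer, k))
      acc <- if (is.null(acc)) sp$power else acc + sp$power
    }
    rows[[r]] <- data.frame(row = r, frequency = sp$frequency,
                            power = acc / jc, count = sp$count)
  }
  out <- do.call(rbind, rows)
  pmax_ <- max(out$power)
  if (pmax_ == 0) {
    warning("all filter images have zero power (untrained weights?)")
    out$powerDb <- 0
  } else {
    out$powerDb <- 10 * log10(pmax(out$power, .Machine$double.xmin) / pmax_)
  }
  out
}

#' Smooth a similarity trace by local regression
#'
#' Moving local regression (lowess) over the trace, with the window
#' expressed as a fraction of the trace length. A window that would span
#' fewer than two points is clamped, with a warning.
#'
#' @param trace data.frame with columns `iteration` and `similarity` (the
#'   `trace` slot of an [MRTraining-class]), or a numeric vector.
#' @param windowFraction smoother span in (0, 1]; default 0.3.
#' @return data.frame with columns `iteration` and `smoothed`.
#' @export
smoothTrace <- function(trace, windowFraction = 0.3) {
  if (is.numeric(trace))
    trace <- data.frame(iteration = seq_along(trace), similarity = trace)
  n <- nrow(trace)
  if (n == 0L) stop("empty trace")
  f <- windowFraction
  if (f > 1) { warning("smoothing window larger than trace; clamped"); f <- 1 }
  if (f * n < 2) { warning("smoothing window spans < 2 points; clamped"); f <- min(1, 2 / n) }
  s <- stats::lowess(trace$iteration, trace$similarity, f = f)
  data.frame(iteration = s$x, smoothed = s$y)
}

#' Mosaic of regenerated filter images
#'
#' Arranges the regenerated receptive-field image of every kernel of a
#' layer in the bank layout (coarse rows on top), each tile min-max
#' normalised, separated by one-pixel gutters.
#'
#' @param stack an [MRStack-class].
#' @param layer layer index.
#' @param pad gutter width in pixels.
#' @return numeric matrix in `[0, 1]`.
#' @export
renderFilters <- function(stack, layer, pad = 1L) {
  stopifnot(is(stack, "MRStack"))
  lay <- stack@layers[[layer]]
  cov <- stack@geometry[[layer]]@pixelCoverage
  jr <- lay@bankShape[1L]; jc <- lay@bankShape[2L]
  H <- jr * cov + (jr + 1L) * pad
  W <- jc * cov + (jc + 1L) * pad
  out <- matrix(0, H, W)
  for (r in seq_len(jr)) for (cc in seq_len(jc)) {
    k <- (r - 1L) * jc + cc
    tile <- minMax(visualizeFilter(stack, layer, k))
    r0 <- pad + (r - 1L) * (cov + pad)
    c0 <- pad + (cc - 1L) * (cov + pad)
    out[r0 + seq_len(cov), c0 + seq_len(cov)] <- tile
  }
  out
}
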