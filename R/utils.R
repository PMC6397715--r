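# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Min-max rescale to [0, 1]; a constant input maps to all zeros.
minMax <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L]) return(array(0, dim = dim(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Read a grayscale image from a PNG file
#'
#' Colour images are converted to luminance with the standard
#' 0.299/0.587/0.114 weights; an alpha channel is dropped. Intensities are
#' returned in `[0, 1]`.
#'
#' @param path path to a PNG file.
#' @return numeric matrix of intensities.
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) return(a)
  if (dim(a)[3L] >= 3L)
    return(0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L])
  a[, , 1L]
}

#' Write a matrix as a grayscale PNG file
#'
#' The matrix is min-max rescaled to `[0, 1]` unless `rescale = FALSE`, in
#' which case values are clamped.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param rescale rescale to the full intensity range (default TRUE).
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path, rescale = TRUE) {
  stopifnot(is.matrix(image))
  img <- if (rescale) minMax(image) else pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}
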