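#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric or integer matrix (or vector with `nrow`/`ncol`)
#'   of raw intensities, integers in \[0, 255\].
#' @param nrow,ncol optional dimensions when `pixels` is a plain vector.
#' @return a [GrayImage-class].
#' @examples
#' grayImage(matrix(c(0L, 128L, 255L, 7L), 2, 2))
#' @export
grayImage <- function(pixels, nrow = NULL, ncol = NULL) {
  if (!is.matrix(pixels)) {
    if (is.null(nrow) && is.null(ncol))
      stop("pixels must be a matrix, or provide nrow/ncol")
    pixels <- matrix(pixels, nrow = nrow %||% (length(pixels) %/% ncol),
                     ncol = ncol %||% (length(pixels) %/% nrow))
  }
  if (is.double(pixels) && (anyNA(pixels) || any(pixels != trunc(pixels))))
    stop("pixel values must be integers in [0, 255]")
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels = pixels)
}

#' Construct a BinaryMask from a matrix
#'
#' @param pixels matrix (or logical matrix) of \{0, 1\}; TRUE/1 marks object.
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(pixels) {
  if (is.logical(pixels)) pixels[] <- as.integer(pixels)
  storage.mode(pixels) <- "integer"
  new("BinaryMask", pixels = pixels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gray-level histogram of an image, on the shifted \[1, L\] scale
#'
#' Counts pixels per gray level after shifting raw intensities \[0, 255\] to
#' levels \[1, 256\] (level i holds raw intensity i - 1). All estimators and
#' the cross-entropy objective work on the shifted scale, where every level
#' is strictly positive.
#'
#' @param image a [GrayImage-class].
#' @return an [IntensityHistogram-class] with 256 levels.
#' @examples
#' h <- computeHistogram(grayImage(matrix(c(0L, 0L, 255L, 128L), 1, 4)))
#' counts(h)[c(1, 129, 256)]
#' @export
computeHistogram <- function(image) {
  stopifnot(is(image, "GrayImage"))
  cnt <- tabulate(as.vector(image@pixels) + 1L, nbins = 256L)
  new("IntensityHistogram", counts = as.integer(cnt), nLevels = 256L,
      total = length(image@pixels))
}

#' Split a histogram into its two mode vectors at a candidate threshold
#'
#' The two "modes" are the per-pixel multisets of shifted levels below/above
#' the candidate threshold t: mode 1 holds one entry per pixel with level
#' <= t, mode 2 one entry per pixel with level > t, both sorted
#' non-decreasing. An empty mode is returned as a zero-length vector — the
#' signal that the candidate t leaves one class empty (the threshold search
#' skips such candidates).
#'
#' @param histogram an [IntensityHistogram-class].
#' @param t candidate threshold on the shifted scale, in \[1, L-1\].
#' @return list with integer vectors `mode1`, `mode2` (shifted levels).
#' @examples
#' img <- grayImage(matrix(c(9L, 9L, 199L, 199L, 199L), 1, 5))
#' splitModes(computeHistogram(img), t = 100)
#' @export
splitModes <- function(histogram, t) {
  stopifnot(is(histogram, "IntensityHistogram"))
  L <- histogram@nLevels
  if (length(t) != 1L || is.na(t) || t != trunc(t) || t < 1 || t > L - 1)
    stop("t must be an integer threshold in [1, ", L - 1, "]")
  t <- as.integer(t)
  cnt <- histogram@counts
  list(mode1 = rep.int(seq_len(t), cnt[seq_len(t)]),
       mode2 = rep.int(seq.int(t + 1L, L), cnt[seq.int(t + 1L, L)]))
}

#' Threshold an image into a binary mask
#'
#' A pixel becomes object (1) when its raw intensity strictly exceeds the
#' raw-scale threshold; ties at the threshold go to background.
#'
#' @param image a [GrayImage-class].
#' @param tRaw threshold on the raw \[0, 255\] intensity scale.
#' @return a [BinaryMask-class] of the same dimensions.
#' @examples
#' pixels(applyThreshold(grayImage(matrix(c(3L, 9L), 1, 2)), tRaw = 5))
#' @export
applyThreshold <- function(image, tRaw) {
  stopifnot(is(image, "GrayImage"))
  if (length(tRaw) != 1L || is.na(tRaw) || tRaw < 0 || tRaw > 255)
    stop("tRaw must lie in [0, 255]")
  m <- image@pixels > tRaw
  storage.mode(m) <- "integer"
  new("BinaryMask", pixels = m)
}
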