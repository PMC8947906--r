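#' Read an 8-bit single-channel grayscale image
#'
#' Supports PNG, TIFF and PGM (both ASCII `P2` and binary `P5`, maxval
#' <= 255). Multi-channel inputs (RGB, gray+alpha) are rejected — there is
#' no silent color-to-gray conversion — as are bit depths above 8.
#'
#' @param path file path; the format is taken from the extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    pgm = return(readPGM(path)),
    stop("unsupported image format: .", ext, " (use PNG, TIFF or PGM)"))
  if (length(dim(arr)) == 3L && dim(arr)[3] > 1L)
    stop("multi-channel image rejected: expected single-channel grayscale")
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  px <- arr * 255
  if (max(abs(px - round(px))) > 1e-6)
    stop("only 8-bit images are supported")
  grayImage(matrix(as.integer(round(px)), nrow(arr), ncol(arr)))
}

readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval; '#' starts a comment
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (expected P2 or P5)")
  w <- as.integer(readToken())
  h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1 || h < 1)
    stop("malformed PGM header")
  if (maxval > 255) stop("only 8-bit PGM (maxval <= 255) is supported")
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data")
  grayImage(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Object pixels (1) are written as 255, background as 0, matching the
#' convention that segmented objects appear white in the output image.
#'
#' @param mask a [BinaryMask-class].
#' @param path output file path (`.png`).
#' @return invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  png::writePNG(mask@pixels * 1.0, path)
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param image a [GrayImage-class].
#' @param path output file path (`.png`).
#' @return invisibly, `path`.
#' @export
writeImagePNG <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}
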