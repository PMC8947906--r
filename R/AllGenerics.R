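#' Accessors for the core classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `pixels()` returns the underlying integer matrix of a [GrayImage-class] or
#' [BinaryMask-class]; `counts()` and `totalCount()` expose an
#' [IntensityHistogram-class]; `thresholdRaw()`, `thresholdShifted()`,
#' `classMeans()`, `objectiveProfile()` and `estimator()` expose a
#' [ThresholdResult-class]; `estimatorMethod()` and `estimatorParam()` expose
#' an [EstimatorSpec-class].
#'
#' @param x an object of the documented class.
#' @return `pixels`: integer matrix; `counts`: integer vector of length 256;
#'   `totalCount`: integer; `thresholdRaw`/`thresholdShifted`: numeric;
#'   `classMeans`: named numeric vector `c(mu1, mu2)`; `objectiveProfile`:
#'   numeric vector over candidate levels (NA at infeasible ones);
#'   `estimator`: [EstimatorSpec-class]; `estimatorMethod`: character;
#'   `estimatorParam`: numeric (NA for parameter-free methods).
#' @name accessors
#' @examples
#' img <- grayImage(matrix(c(10L, 10L, 200L, 200L), 2, 2))
#' h <- computeHistogram(img)
#' totalCount(h)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname accessors
#' @export
setGeneric("thresholdRaw", function(x) standardGeneric("thresholdRaw"))

#' @rdname accessors
#' @export
setGeneric("thresholdShifted", function(x) standardGeneric("thresholdShifted"))

#' @rdname accessors
#' @export
setGeneric("classMeans", function(x) standardGeneric("classMeans"))

#' @rdname accessors
#' @export
setGeneric("objectiveProfile", function(x) standardGeneric("objectiveProfile"))

#' @rdname accessors
#' @export
setGeneric("estimator", function(x) standardGeneric("estimator"))

#' @rdname accessors
#' @export
setGeneric("estimatorMethod", function(x) standardGeneric("estimatorMethod"))

#' @rdname accessors
#' @export
setGeneric("estimatorParam", function(x) standardGeneric("estimatorParam"))

#' @rdname accessors
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("counts", "IntensityHistogram", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("totalCount", "IntensityHistogram", function(x) x@total)

#' @rdname accessors
#' @export
setMethod("thresholdRaw", "ThresholdResult", function(x) x@tRaw)

#' @rdname accessors
#' @export
setMethod("thresholdShifted", "ThresholdResult", function(x) x@tShifted)

#' @rdname accessors
#' @export
setMethod("classMeans", "ThresholdResult",
          function(x) c(mu1 = x@mu1, mu2 = x@mu2))

#' @rdname accessors
#' @export
setMethod("objectiveProfile", "ThresholdResult", function(x) x@objective)

#' @rdname accessors
#' @export
setMethod("estimator", "ThresholdResult", function(x) x@spec)

#' @rdname accessors
#' @export
setMethod("estimatorMethod", "EstimatorSpec", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("estimatorParam", "EstimatorSpec", function(x) {
  switch(x@method,
         alpha_trim = x@halfTrim,
         contraharmonic = x@order,
         NA_real_)
})

#' @describeIn accessors image dimensions `c(height, width)`.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn accessors mask dimensions `c(height, width)`.
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  r <- range(object@pixels)
  cat(sprintf("GrayImage %d x %d, intensity range [%d, %d]\n",
              d[1], d[2], r[1], r[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask %d x %d, %d object pixel(s) (%.1f%%)\n",
              d[1], d[2], sum(object@pixels),
              100 * mean(object@pixels)))
})

setMethod("show", "IntensityHistogram", function(object) {
  occ <- which(object@counts > 0L)
  cat(sprintf(
    "IntensityHistogram: %d levels, %d pixels, %d occupied level(s) in [%d, %d] (shifted)\n",
    object@nLevels, object@total, length(occ), min(occ), max(occ)))
})

setMethod("show", "EstimatorSpec", function(object) {
  cat("EstimatorSpec:", formatEstimatorSpec(object), "\n")
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf(
    "ThresholdResult [%s]\n  threshold: %d (raw), %d (shifted)\n  class means (shifted): mu1 = %.4f, mu2 = %.4f%s\n  %d feasible candidate level(s)\n",
    formatEstimatorSpec(object@spec), object@tRaw, object@tShifted,
    object@mu1, object@mu2,
    if (object@meansOrdered) "" else "  [warning: mu1 >= mu2]",
    length(object@validT)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: %dx%d %s, means %g/%g, sigmas %g/%g, salt %g, pepper %g, grayzone %d, seed %d\n",
    object@height, object@width, object@shape, object@bgMean, object@fgMean,
    object@bgSigma, object@fgSigma, object@saltDensity, object@pepperDensity,
    object@grayzoneWidth, object@seed))
})
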