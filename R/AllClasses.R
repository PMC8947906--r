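#' @import methods
NULL

#' GrayImage: an 8-bit single-channel grayscale image
#'
#' Thin S4 wrapper around an integer matrix with raw intensities in
#' \[0, 255\]. Rows index image height, columns width.
#'
#' @slot pixels integer matrix of intensities in \[0, 255\].
#' @seealso [grayImage()], [computeHistogram()], [applyThreshold()]
#' @exportClass GrayImage
setClass("GrayImage", representation(pixels = "matrix"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (length(p) == 0L) return("image must contain at least one pixel")
    if (anyNA(p)) return("pixels must not contain NA")
    if (any(p != trunc(p))) return("pixel values must be integers")
    if (any(p < 0 | p > 255)) return("pixel values must lie in [0, 255]")
    TRUE
  })

#' BinaryMask: a two-class segmentation mask
#'
#' Integer matrix of \{0, 1\}: 1 marks object (foreground), 0 background.
#' On file output foreground is written as 255.
#'
#' @slot pixels integer matrix of \{0, 1\}.
#' @seealso [binaryMask()], [applyThreshold()], [writeMask()]
#' @exportClass BinaryMask
setClass("BinaryMask", representation(pixels = "matrix"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (length(p) == 0L) return("mask must contain at least one pixel")
    if (anyNA(p)) return("pixels must not contain NA")
    if (!all(p %in% c(0, 1))) return("mask values must be exactly 0 or 1")
    TRUE
  })

#' IntensityHistogram: per-level pixel counts on the shifted scale
#'
#' Gray-level histogram over shifted levels i in \[1, L\] (L = 256 for 8-bit
#' input), where shifted level i corresponds to raw intensity i - 1. The
#' shift keeps every level strictly positive so that logarithms, reciprocals
#' and powers taken by the estimators and the cross-entropy objective are
#' well defined.
#'
#' @slot counts integer vector of length `nLevels`; `counts[i]` is the number
#'   of pixels at shifted level i.
#' @slot nLevels number of gray levels L (256).
#' @slot total total pixel count (equals `sum(counts)`).
#' @seealso [computeHistogram()], [splitModes()], [findThreshold()]
#' @exportClass IntensityHistogram
setClass("IntensityHistogram",
  representation(counts = "integer", nLevels = "integer", total = "integer"),
  validity = function(object) {
    if (length(object@counts) != object@nLevels)
      return("counts must have length nLevels")
    if (anyNA(object@counts) || any(object@counts < 0L))
      return("counts must be non-negative integers")
    if (sum(object@counts) != object@total)
      return("total must equal sum(counts)")
    TRUE
  })

#' EstimatorSpec: which class-mean filter to use, and its parameter
#'
#' Identifies one of the mean estimation filters applied to both histogram
#' modes: `"classical"` (arithmetic), `"alpha_trim"` (needs `halfTrim`, the
#' pixel count d/2 removed from each end of the sorted mode), `"harmonic"`,
#' `"contraharmonic"` (needs `order`, the filter order Q) or `"geometric"`.
#' The placeholder method `"lognormal"` denotes a comparison configuration
#' that this package does not implement; it is carried through sweep grids
#' flagged as unsupported.
#'
#' @slot method character, one of `"classical"`, `"alpha_trim"`,
#'   `"harmonic"`, `"contraharmonic"`, `"geometric"`, `"lognormal"`.
#' @slot halfTrim non-negative integer d/2 (alpha_trim only; NA otherwise).
#' @slot order finite real Q (contraharmonic only; NA otherwise).
#' @seealso [estimatorSpec()], [parseEstimatorSpec()], [sweepGrid()]
#' @exportClass EstimatorSpec
setClass("EstimatorSpec",
  representation(method = "character", halfTrim = "numeric", order = "numeric"),
  prototype(method = "classical", halfTrim = NA_real_, order = NA_real_),
  validity = function(object) {
    methods <- c("classical", "alpha_trim", "harmonic", "contraharmonic",
                 "geometric", "lognormal")
    if (length(object@method) != 1L || !object@method %in% methods)
      return(paste("method must be one of:", paste(methods, collapse = ", ")))
    if (object@method == "alpha_trim") {
      if (is.na(object@halfTrim)) return("alpha_trim requires halfTrim (d/2)")
      if (object@halfTrim < 0 || object@halfTrim != trunc(object@halfTrim))
        return("halfTrim must be a non-negative integer")
    } else if (!is.na(object@halfTrim)) {
      return("halfTrim is only meaningful for method 'alpha_trim'")
    }
    if (object@method == "contraharmonic") {
      if (is.na(object@order) || !is.finite(object@order))
        return("contraharmonic requires a finite order Q")
    } else if (!is.na(object@order)) {
      return("order is only meaningful for method 'contraharmonic'")
    }
    TRUE
  })

#' ThresholdResult: the MCET optimum and its diagnostics
#'
#' Returned by [findThreshold()]. Holds the minimizing threshold on both the
#' raw \[0, 255\] and the shifted \[1, L\] scale, the two estimated class means
#' at the optimum (shifted scale), the full objective profile n(t) over the
#' candidate range (NA where a candidate was infeasible under the estimator),
#' the candidate levels actually evaluated, and the estimator used.
#'
#' @slot tRaw optimal threshold on the raw intensity scale (t_shifted - 1).
#' @slot tShifted optimal threshold on the shifted \[1, L\] scale.
#' @slot mu1,mu2 estimated class means at the optimum (shifted scale).
#' @slot objective numeric vector of n(t) for t = 1..L-1; NA at infeasible t.
#' @slot validT integer vector of the feasible candidate levels.
#' @slot spec the [EstimatorSpec-class] used.
#' @slot meansOrdered FALSE when mu1 >= mu2 at the optimum (possible for
#'   extreme contraharmonic orders; means are reported unclamped).
#' @seealso [findThreshold()], [segmentImage()]
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(tRaw = "numeric", tShifted = "numeric",
                 mu1 = "numeric", mu2 = "numeric",
                 objective = "numeric", validT = "integer",
                 spec = "EstimatorSpec", meansOrdered = "logical"),
  validity = function(object) {
    if (object@tShifted != object@tRaw + 1)
      return("tShifted must equal tRaw + 1")
    if (!(object@tShifted %in% object@validT))
      return("the chosen threshold must be a feasible candidate")
    TRUE
  })

#' FixtureSpec: parameters of a synthetic bimodal test image
#'
#' Describes a two-class grayscale image: a bright object (`shape`) on a dark
#' background, Gaussian within-class noise, optional salt (255) and pepper
#' (0) impulse noise, and an optional "grayness" transition band of blended
#' intermediate intensities at the object boundary. These are exactly the
#' nuisance structures the robust mean estimators are designed to exclude.
#'
#' @slot height,width image dimensions (pixels).
#' @slot bgMean,fgMean background/foreground class means, raw \[0, 255\],
#'   with `bgMean < fgMean` (object brighter, the lesion/tumor convention).
#' @slot bgSigma,fgSigma Gaussian within-class standard deviations.
#' @slot saltDensity,pepperDensity impulse probabilities per pixel in
#'   \[0, 0.5\]; their sum must stay below 1.
#' @slot grayzoneWidth width (pixels) of the blended transition band.
#' @slot shape object shape: `"disk"`, `"rectangle"` or `"blob"`.
#' @slot seed integer seed; generation is bit-reproducible for a fixed seed.
#' @seealso [fixtureSpec()], [generateFixture()]
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(height = "integer", width = "integer",
                 bgMean = "numeric", fgMean = "numeric",
                 bgSigma = "numeric", fgSigma = "numeric",
                 saltDensity = "numeric", pepperDensity = "numeric",
                 grayzoneWidth = "integer", shape = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@height < 1L || object@width < 1L)
      return("height and width must be positive")
    if (object@bgMean >= object@fgMean)
      return("bgMean must be strictly less than fgMean (foreground brighter)")
    if (object@bgMean < 0 || object@fgMean > 255)
      return("class means must lie in [0, 255]")
    if (object@bgSigma < 0 || object@fgSigma < 0)
      return("sigmas must be non-negative")
    if (object@saltDensity < 0 || object@saltDensity > 0.5 ||
        object@pepperDensity < 0 || object@pepperDensity > 0.5)
      return("impulse densities must lie in [0, 0.5]")
    if (object@saltDensity + object@pepperDensity >= 1)
      return("saltDensity + pepperDensity must be < 1")
    if (object@grayzoneWidth < 0L)
      return("grayzoneWidth must be non-negative")
    if (!object@shape %in% c("disk", "rectangle", "blob"))
      return("shape must be one of disk, rectangle, blob")
    TRUE
  })
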