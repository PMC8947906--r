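#' The minimum cross-entropy objective at a candidate threshold
#'
#' With the image-constant term dropped, the cross entropy between the image
#' and its two-class thresholded version reduces (natural log throughout) to
#'
#'   n(t) = -sum_\{i<=t\} i h(i) log(mu1) - sum_\{i>t\} i h(i) log(mu2)
#'
#' over shifted levels i. The optimal threshold minimizes n(t). The class
#' means may come from any of the mean-filter estimators; this function only
#' evaluates the objective for a given pair.
#'
#' @param histogram an [IntensityHistogram-class].
#' @param t candidate threshold on the shifted scale, in \[1, L-1\].
#' @param mu1,mu2 positive class means (shifted scale).
#' @return n(t), a numeric scalar.
#' @examples
#' img <- grayImage(matrix(c(rep(10L, 2), rep(200L, 3)), 1, 5))
#' h <- computeHistogram(img)
#' mcetObjective(h, 100, 11, 201)  # == -2*11*log(11) - 3*201*log(201)
#' @export
mcetObjective <- function(histogram, t, mu1, mu2) {
  stopifnot(is(histogram, "IntensityHistogram"))
  if (!is.finite(mu1) || !is.finite(mu2) || mu1 <= 0 || mu2 <= 0)
    stop("class means must be positive and finite")
  L <- histogram@nLevels
  if (length(t) != 1L || is.na(t) || t != trunc(t) || t < 1 || t > L - 1)
    stop("t must be an integer threshold in [1, ", L - 1, "]")
  t <- as.integer(t)
  m <- histogram@counts * seq_len(L)  # first-moment contributions i*h(i)
  -sum(m[seq_len(t)]) * log(mu1) - sum(m[seq.int(t + 1L, L)]) * log(mu2)
}

#' Find the MCET-optimal threshold under a chosen mean estimator
#'
#' Sweeps every candidate threshold t in \[1, L-1\], estimates both class
#' means with the requested filter, evaluates the cross-entropy objective
#' n(t), and returns the minimizer. Candidates where either class is empty,
#' where the trim exceeds a class size, or where the contraharmonic power
#' sums are non-finite are infeasible and skipped (their profile entries are
#' NA). Ties in n(t) are broken toward the smallest t.
#'
#' @param histogram an [IntensityHistogram-class] with at least two occupied
#'   levels.
#' @param spec an [EstimatorSpec-class] (the `"lognormal"` placeholder is
#'   rejected as unsupported).
#' @return a [ThresholdResult-class].
#' @examples
#' img <- grayImage(matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10))
#' res <- findThreshold(computeHistogram(img), estimatorSpec("classical"))
#' thresholdRaw(res); classMeans(res)
#' @export
findThreshold <- function(histogram, spec) {
  stopifnot(is(histogram, "IntensityHistogram"), is(spec, "EstimatorSpec"))
  if (spec@method == "lognormal")
    stop("unsupported estimator: lognormal is a comparison placeholder")
  cnt <- histogram@counts
  L <- histogram@nLevels
  if (sum(cnt > 0L) < 2L) stop("degenerate histogram: fewer than 2 occupied levels")
  lev <- seq_len(L)
  moment <- cumsum(cnt * lev)        # A1(t) = sum_{i<=t} i*h(i)
  momentTot <- moment[L]
  cc <- cumsum(cnt)
  total <- histogram@total
  d2 <- if (spec@method == "alpha_trim") spec@halfTrim else 0

  obj <- rep(NA_real_, L - 1L)
  mu1s <- rep(NA_real_, L - 1L)
  mu2s <- rep(NA_real_, L - 1L)
  for (t in seq_len(L - 1L)) {
    n1 <- cc[t]; n2 <- total - n1
    if (n1 - 2 * d2 < 1 || n2 - 2 * d2 < 1) next
    i1 <- seq_len(t); i2 <- seq.int(t + 1L, L)
    mu <- tryCatch(
      c(meanFromCounts(cnt[i1], lev[i1], spec),
        meanFromCounts(cnt[i2], lev[i2], spec)),
      error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) next
    obj[t] <- -moment[t] * log(mu[1]) - (momentTot - moment[t]) * log(mu[2])
    mu1s[t] <- mu[1]; mu2s[t] <- mu[2]
  }
  validT <- which(!is.na(obj))
  if (length(validT) == 0L)
    stop("no feasible threshold under this estimator")
  best <- validT[which.min(obj[validT])]  # ties -> smallest t
  ordered <- mu1s[best] < mu2s[best]
  if (!ordered)
    warning("class means not ordered (mu1 >= mu2) at the selected threshold")
  new("ThresholdResult",
      tRaw = best - 1, tShifted = as.numeric(best),
      mu1 = mu1s[best], mu2 = mu2s[best],
      objective = obj, validT = as.integer(validT),
      spec = spec, meansOrdered = ordered)
}

#' Segment an image end to end
#'
#' Composes [computeHistogram()], [findThreshold()] and [applyThreshold()]:
#' builds the histogram, finds the MCET-optimal threshold under the chosen
#' mean estimator, and thresholds the image.
#'
#' @param image a [GrayImage-class].
#' @param spec an [EstimatorSpec-class].
#' @return list with elements `mask` (a [BinaryMask-class]) and `result`
#'   (the [ThresholdResult-class] diagnostics).
#' @examples
#' img <- grayImage(matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10))
#' seg <- segmentImage(img, estimatorSpec("classical"))
#' seg$result
#' @export
segmentImage <- function(image, spec) {
  stopifnot(is(image, "GrayImage"))
  res <- findThreshold(computeHistogram(image), spec)
  list(mask = applyThreshold(image, res@tRaw), result = res)
}

#' Serialize a ThresholdResult to JSON
#'
#' @param result a [ThresholdResult-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @param profile include the full objective profile (default TRUE).
#' @return invisibly the JSON string.
#' @export
thresholdResultJSON <- function(result, path = NULL, profile = TRUE) {
  stopifnot(is(result, "ThresholdResult"))
  x <- list(
    t_raw = result@tRaw,
    t_shifted = result@tShifted,
    mu1 = result@mu1,
    mu2 = result@mu2,
    means_ordered = result@meansOrdered,
    estimator = formatEstimatorSpec(result@spec))
  if (profile) {
    x$valid_t <- result@validT
    x$objective <- result@objective
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
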