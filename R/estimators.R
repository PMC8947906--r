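#' Construct an estimator specification
#'
#' @param method one of `"classical"`, `"alpha_trim"`, `"harmonic"`,
#'   `"contraharmonic"`, `"geometric"`, or the unsupported placeholder
#'   `"lognormal"`.
#' @param halfTrim non-negative integer d/2, the number of pixels removed
#'   from each end of the sorted mode (alpha_trim only). This is an absolute
#'   pixel count, not a fraction: trim values scale with image size.
#' @param order finite real Q, the contraharmonic filter order. Q > 0
#'   suppresses pepper (low) outliers, Q < 0 salt (high) outliers; Q = 0
#'   recovers the arithmetic mean and Q = -1 the harmonic mean.
#' @return an [EstimatorSpec-class].
#' @examples
#' estimatorSpec("alpha_trim", halfTrim = 50)
#' estimatorSpec("contraharmonic", order = -0.5)
#' @export
estimatorSpec <- function(method, halfTrim = NULL, order = NULL) {
  new("EstimatorSpec", method = method,
      halfTrim = if (is.null(halfTrim)) NA_real_ else as.numeric(halfTrim),
      order = if (is.null(order)) NA_real_ else as.numeric(order))
}

#' Parse / format the estimator string grammar
#'
#' Grammar: `"<method>[:<param>]"`, e.g. `"classical"`, `"harmonic"`,
#' `"geometric"`, `"contraharmonic:-0.5"`, `"alpha_trim:55"`. Decimal
#' parsing is locale-independent (`.` is the decimal mark).
#'
#' @param text a single estimator string.
#' @return [parseEstimatorSpec()]: an [EstimatorSpec-class];
#'   [formatEstimatorSpec()]: the canonical string.
#' @examples
#' parseEstimatorSpec("contraharmonic:-0.5")
#' formatEstimatorSpec(estimatorSpec("alpha_trim", halfTrim = 55))
#' @export
parseEstimatorSpec <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text))
    stop("estimator string must be a single character value")
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  method <- parts[1]
  if (length(parts) > 2L)
    stop("malformed estimator string: ", text)
  param <- if (length(parts) == 2L) {
    v <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(v)) stop("non-numeric estimator parameter in: ", text)
    v
  } else NULL
  spec <- switch(method,
    alpha_trim = {
      if (is.null(param)) stop("alpha_trim requires a parameter, e.g. alpha_trim:50")
      estimatorSpec("alpha_trim", halfTrim = param)
    },
    contraharmonic = {
      if (is.null(param)) stop("contraharmonic requires a parameter, e.g. contraharmonic:-0.5")
      estimatorSpec("contraharmonic", order = param)
    },
    classical = , harmonic = , geometric = , lognormal = {
      if (!is.null(param)) stop(method, " takes no parameter")
      estimatorSpec(method)
    },
    stop("unknown estimator method: ", method))
  spec
}

#' @rdname parseEstimatorSpec
#' @param spec an [EstimatorSpec-class].
#' @export
formatEstimatorSpec <- function(spec) {
  stopifnot(is(spec, "EstimatorSpec"))
  switch(spec@method,
         alpha_trim = sprintf("alpha_trim:%g", spec@halfTrim),
         contraharmonic = sprintf("contraharmonic:%g", spec@order),
         spec@method)
}

checkMode <- function(mode) {
  if (length(mode) == 0L) stop("empty class")
  if (anyNA(mode) || any(mode < 1)) stop("mode values must be >= 1")
}

#' Class-mean estimators on a mode vector
#'
#' The five mean filters, adapted from their sliding-window image forms to
#' operate on a histogram mode vector (the sorted multiset of shifted
#' intensity levels of one class). All return a real mean on the shifted
#' scale; all error on an empty mode.
#'
#' * `classicalMean`: the arithmetic mean, identical to the count-weighted
#'   histogram mean of the Gaussian-distribution formulation.
#' * `alphaTrimmedMean`: drops the `halfTrim` lowest and `halfTrim` highest
#'   entries of the sorted mode (positional trimming, by pixel count), then
#'   averages the remainder over `length - 2*halfTrim` entries. Robust to
#'   mixed salt-and-pepper plus Gaussian noise and to gray transition pixels.
#' * `harmonicMean`: `length / sum(1/values)`; suppresses salt (high)
#'   impulses but not pepper.
#' * `contraharmonicMean`: `sum(values^(Q+1)) / sum(values^Q)`; Q > 0
#'   suppresses pepper, Q < 0 salt. Powers are taken on shifted levels
#'   (all >= 1) and non-finite intermediates raise an error.
#' * `geometricMean`: `exp(mean(log(values)))`.
#'
#' @param mode integer/numeric vector of shifted levels (values >= 1).
#' @param halfTrim non-negative integer d/2 (pixels trimmed per end).
#' @param order finite real Q.
#' @return the estimated class mean (numeric scalar).
#' @examples
#' classicalMean(c(2, 2, 4, 4))            # 3
#' alphaTrimmedMean(c(1, 2, 3, 4, 5, 100), halfTrim = 1)  # 3.5
#' harmonicMean(c(2, 8))                   # 3.2
#' contraharmonicMean(c(1, 2, 3), order = 1)  # 14/6
#' geometricMean(c(2, 8))                  # 4
#' @name meanEstimators
NULL

#' @rdname meanEstimators
#' @export
classicalMean <- function(mode) {
  checkMode(mode)
  sum(mode) / length(mode)
}

#' @rdname meanEstimators
#' @export
alphaTrimmedMean <- function(mode, halfTrim) {
  checkMode(mode)
  if (length(halfTrim) != 1L || is.na(halfTrim) || halfTrim < 0 ||
      halfTrim != trunc(halfTrim))
    stop("halfTrim must be a non-negative integer")
  n <- length(mode)
  if (n - 2 * halfTrim < 1) stop("trim exceeds class size")
  if (halfTrim == 0) return(sum(mode) / n)
  v <- sort(mode)
  keep <- v[(halfTrim + 1):(n - halfTrim)]
  sum(keep) / (n - 2 * halfTrim)
}

#' @rdname meanEstimators
#' @export
harmonicMean <- function(mode) {
  checkMode(mode)
  length(mode) / sum(1 / mode)
}

#' @rdname meanEstimators
#' @export
contraharmonicMean <- function(mode, order) {
  checkMode(mode)
  if (length(order) != 1L || !is.finite(order))
    stop("order Q must be a finite real")
  num <- sum(mode^(order + 1))
  den <- sum(mode^order)
  out <- num / den
  if (!is.finite(out)) stop("unstable order: non-finite contraharmonic mean")
  out
}

#' @rdname meanEstimators
#' @export
geometricMean <- function(mode) {
  checkMode(mode)
  exp(sum(log(mode)) / length(mode))
}

# Count-weighted trimmed mean over histogram counts cnt at levels lev
# (both restricted to one class). Equivalent to alphaTrimmedMean on the
# materialized mode vector, but O(L) via cumulative counts.
trimmedMeanFromCounts <- function(cnt, lev, halfTrim) {
  n <- sum(cnt)
  r <- n - 2 * halfTrim
  if (r < 1) stop("trim exceeds class size")
  total <- sum(cnt * lev)
  if (halfTrim == 0) return(total / n)
  cc <- cumsum(cnt)
  cs <- cumsum(cnt * lev)
  # sum of the k smallest entries of the multiset
  tailSum <- function(k) {
    if (k == 0) return(0)
    j <- which(cc >= k)[1]
    base <- if (j > 1) cs[j - 1] else 0
    below <- if (j > 1) cc[j - 1] else 0
    base + (k - below) * lev[j]
  }
  low <- tailSum(halfTrim)
  # k largest = reverse the class
  ccR <- cumsum(rev(cnt))
  csR <- cumsum(rev(cnt) * rev(lev))
  j <- which(ccR >= halfTrim)[1]
  base <- if (j > 1) csR[j - 1] else 0
  below <- if (j > 1) ccR[j - 1] else 0
  high <- base + (halfTrim - below) * rev(lev)[j]
  (total - low - high) / r
}

# One estimator evaluated from histogram counts restricted to a class.
# Identical in value to the mode-vector functions; count-weighted for speed.
meanFromCounts <- function(cnt, lev, spec) {
  n <- sum(cnt)
  if (n == 0L) stop("empty class")
  switch(spec@method,
    classical = sum(cnt * lev) / n,
    alpha_trim = trimmedMeanFromCounts(cnt, lev, spec@halfTrim),
    harmonic = n / sum(cnt / lev),
    contraharmonic = {
      q <- spec@order
      out <- sum(cnt * lev^(q + 1)) / sum(cnt * lev^q)
      if (!is.finite(out)) stop("unstable order: non-finite contraharmonic mean")
      out
    },
    geometric = exp(sum(cnt * log(lev)) / n),
    stop("unsupported estimator method: ", spec@method))
}

#' Estimate both class means at a candidate threshold
#'
#' Applies the same estimator, with the same parameter, to the two histogram
#' modes induced by the candidate threshold t (levels \[1, t\] and
#' \[t+1, L\]). Means are count-weighted over the histogram, which is exactly
#' the estimator applied to the per-pixel mode vector. Contraharmonic means
#' are never clamped into their class interval; ordering violations are the
#' caller's to inspect.
#'
#' @param histogram an [IntensityHistogram-class].
#' @param t candidate threshold on the shifted scale, in \[1, L-1\].
#' @param spec an [EstimatorSpec-class].
#' @return named numeric vector `c(mu1, mu2)` on the shifted scale.
#' @examples
#' img <- grayImage(matrix(c(rep(10L, 2), rep(200L, 3)), 1, 5))
#' estimateMeans(computeHistogram(img), t = 100, estimatorSpec("classical"))
#' @export
estimateMeans <- function(histogram, t, spec) {
  stopifnot(is(histogram, "IntensityHistogram"), is(spec, "EstimatorSpec"))
  L <- histogram@nLevels
  if (length(t) != 1L || is.na(t) || t != trunc(t) || t < 1 || t > L - 1)
    stop("t must be an integer threshold in [1, ", L - 1, "]")
  t <- as.integer(t)
  cnt <- histogram@counts
  lev <- seq_len(L)
  i1 <- seq_len(t)
  i2 <- seq.int(t + 1L, L)
  c(mu1 = meanFromCounts(cnt[i1], lev[i1], spec),
    mu2 = meanFromCounts(cnt[i2], lev[i2], spec))
}
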