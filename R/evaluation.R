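#' Image uniformity (unsupervised)
#'
#' Levine–Nazif region uniformity of a thresholded image: one minus the sum
#' of the within-region intensity variances (population variances, divisor
#' n) of the two regions induced by the threshold, normalized by
#' Z = (I_max - I_min)^2 / 2 over the whole image, clipped to \[0, 1\].
#' Values near 1 indicate internally homogeneous regions.
#'
#' @param image a [GrayImage-class].
#' @param tRaw threshold on the raw \[0, 255\] scale; region 1 holds pixels
#'   <= tRaw, region 2 pixels > tRaw.
#' @return uniformity score in \[0, 1\].
#' @examples
#' imageUniformity(grayImage(matrix(c(10L, 20L, 200L, 210L), 1, 4)), 100)
#' @export
imageUniformity <- function(image, tRaw) {
  stopifnot(is(image, "GrayImage"))
  px <- as.vector(image@pixels)
  r1 <- px[px <= tRaw]
  r2 <- px[px > tRaw]
  if (length(r1) == 0L || length(r2) == 0L)
    stop("empty region: threshold leaves one class empty")
  z <- (max(px) - min(px))^2 / 2
  if (z == 0) stop("zero dynamic range: constant image")
  popVar <- function(x) mean((x - mean(x))^2)
  iu <- 1 - (popVar(r1) + popVar(r2)) / z
  min(max(iu, 0), 1)
}

#' Region contrast (unsupervised)
#'
#' Normalized separation of the two estimated class means,
#' RC = |mu1 - mu2| / (mu1 + mu2). Near 1 for well-separated classes, 0 for
#' coincident means.
#'
#' @param mu1,mu2 non-negative class means with mu1 + mu2 > 0 (either scale,
#'   as long as both use the same one).
#' @return contrast in \[0, 1\].
#' @examples
#' regionContrast(10, 200)  # 190/210
#' @export
regionContrast <- function(mu1, mu2) {
  if (!is.finite(mu1) || !is.finite(mu2) || mu1 + mu2 <= 0)
    stop("region contrast requires mu1 + mu2 > 0")
  abs(mu1 - mu2) / (mu1 + mu2)
}

# out[i,j] = m[i+dr, j+dc], padded with `fill` beyond the grid
shiftMatrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  okR <- rs >= 1L & rs <= nr
  okC <- cs >= 1L & cs <= nc
  out[okR, okC] <- m[rs[okR], cs[okC]]
  out
}

neighborOffsets <- function() {
  o <- expand.grid(dr = -1:1, dc = -1:1)
  o[!(o$dr == 0 & o$dc == 0), ]
}

#' Inter-region disparity (unsupervised)
#'
#' Compares each region's interior contrast with its contrast across the
#' region border, using pixel contrast c(s, t) = |I(s) - I(t)| / (L - 1)
#' over the 8-connected 3x3 neighborhood W(s). For region R_i with area A_i
#' and border F_i (region pixels with at least one neighbor outside R_i, of
#' size l_i):
#'
#' * interior contrast CI(i) = mean over region pixels of the maximum
#'   contrast to a same-region neighbor (0 for pixels with none);
#' * exterior contrast CE(i) = mean over border pixels of the maximum
#'   contrast to an out-of-region neighbor;
#' * CR(i) = 1 - CI/CE when 0 < CI < CE, CE when CI = 0, and 0 otherwise.
#'
#' The reported scalar is the region-size-weighted average of CR over the
#' two regions. High values mean regions are flat inside and contrasted
#' across the boundary.
#'
#' @param image a [GrayImage-class].
#' @param mask a [BinaryMask-class] with both classes present.
#' @return disparity score in \[0, 1\].
#' @export
interRegionDisparity <- function(image, mask) {
  stopifnot(is(image, "GrayImage"), is(mask, "BinaryMask"))
  if (!identical(dim(image@pixels), dim(mask@pixels)))
    stop("image and mask dimensions differ")
  M <- mask@pixels == 1L
  if (all(M) || !any(M)) stop("single-region mask")
  I <- image@pixels
  offs <- neighborOffsets()

  regionScore <- function(inRegion) {
    maxIn <- matrix(-Inf, nrow(I), ncol(I))
    maxOut <- matrix(-Inf, nrow(I), ncol(I))
    hasOut <- matrix(FALSE, nrow(I), ncol(I))
    for (k in seq_len(nrow(offs))) {
      nI <- shiftMatrix(I, offs$dr[k], offs$dc[k], NA_integer_)
      nIn <- shiftMatrix(inRegion, offs$dr[k], offs$dc[k], NA)
      exists <- !is.na(nI)
      contrast <- abs(I - nI) / 255
      sameSide <- exists & !is.na(nIn) & nIn
      otherSide <- exists & !is.na(nIn) & !nIn
      maxIn[sameSide] <- pmax(maxIn[sameSide], contrast[sameSide])
      maxOut[otherSide] <- pmax(maxOut[otherSide], contrast[otherSide])
      hasOut <- hasOut | otherSide
    }
    area <- sum(inRegion)
    inVals <- maxIn[inRegion]
    ci <- sum(pmax(inVals, 0) * is.finite(inVals)) / area
    border <- inRegion & hasOut
    li <- sum(border)
    if (li == 0L) stop("region with no border pixels")
    ce <- sum(maxOut[border]) / li
    cr <- if (ci == 0) ce else if (ci < ce) 1 - ci / ce else 0
    c(cr = cr, area = area)
  }
  s1 <- regionScore(!M)
  s2 <- regionScore(M)
  unname((s1["cr"] * s1["area"] + s2["cr"] * s2["area"]) /
           (s1["area"] + s2["area"]))
}

#' Confusion counts between a predicted mask and ground truth
#'
#' @param mask,truth [BinaryMask-class] objects of identical dimensions;
#'   1 marks object pixels.
#' @return named integer vector `c(tp, fp, fn, tn)` summing to the pixel
#'   count.
#' @examples
#' m <- binaryMask(matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 1, 6))
#' g <- binaryMask(matrix(c(1L, 1L, 0L, 1L, 1L, 0L), 1, 6))
#' confusionCounts(m, g)
#' @export
confusionCounts <- function(mask, truth) {
  stopifnot(is(mask, "BinaryMask"), is(truth, "BinaryMask"))
  if (!identical(dim(mask@pixels), dim(truth@pixels)))
    stop("mask and truth dimensions differ")
  p <- mask@pixels == 1L
  g <- truth@pixels == 1L
  c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

#' Supervised segmentation metrics from confusion counts
#'
#' Jaccard index tp/(tp+fp+fn), F-score 2PR/(P+R) with precision
#' P = tp/(tp+fp) and recall R = tp/(tp+fn), and accuracy
#' (tp+tn)/(tp+tn+fp+fn). Degenerate cases where precision or recall has a
#' zero denominator (empty prediction or empty truth) raise an
#' "undefined metric" error rather than silently reporting 0, so batch
#' averages stay honest. When tp = 0 with both denominators positive, the
#' F-score is taken at its limit 0.
#'
#' @param counts named vector from [confusionCounts()] (needs elements
#'   `tp`, `fp`, `fn`, `tn`).
#' @return named numeric vector `c(jaccard, f_score, accuracy)`, each in
#'   \[0, 1\]; jaccard always equals f_score / (2 - f_score).
#' @examples
#' supervisedMetrics(c(tp = 2, fp = 1, fn = 2, tn = 1))
#' @export
supervisedMetrics <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts))) stop("counts must name tp, fp, fn, tn")
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  if (tp + fp == 0) stop("undefined metric: empty prediction (tp + fp = 0)")
  if (tp + fn == 0) stop("undefined metric: empty truth (tp + fn = 0)")
  jaccard <- tp / (tp + fp + fn)
  f <- if (tp == 0) 0 else {
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }
  acc <- (tp + tn) / (tp + tn + fp + fn)
  c(jaccard = jaccard, f_score = f, accuracy = acc)
}

#' All quality metrics for one segmentation
#'
#' Convenience wrapper around the unsupervised metrics ([imageUniformity()],
#' [regionContrast()] on the estimated class means, [interRegionDisparity()])
#' and, when ground truth is supplied, the supervised metrics
#' ([confusionCounts()] + [supervisedMetrics()]).
#'
#' @param image the segmented [GrayImage-class].
#' @param segmentation the list returned by [segmentImage()] (elements
#'   `mask`, `result`).
#' @param truth optional ground-truth [BinaryMask-class].
#' @return one-row data.frame with columns `IU`, `RC`, `IRD` and (`JI`, `F`,
#'   `ACC` — NA when `truth` is NULL).
#' @export
segmentationMetrics <- function(image, segmentation, truth = NULL) {
  res <- segmentation$result
  stopifnot(is(res, "ThresholdResult"))
  iu <- imageUniformity(image, res@tRaw)
  rc <- regionContrast(res@mu1, res@mu2)
  ird <- interRegionDisparity(image, segmentation$mask)
  sup <- c(jaccard = NA_real_, f_score = NA_real_, accuracy = NA_real_)
  if (!is.null(truth))
    sup <- supervisedMetrics(confusionCounts(segmentation$mask, truth))
  data.frame(IU = iu, RC = rc, IRD = ird,
             JI = sup[["jaccard"]], F = sup[["f_score"]],
             ACC = sup[["accuracy"]])
}
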