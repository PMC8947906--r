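#' Construct a synthetic-fixture specification
#'
#' Defaults describe the package's reference study condition: a 128x128
#' image with a bright disk (class means 60/180, within-class sigma 15),
#' no impulse noise and no transition band. See [FixtureSpec-class] for the
#' meaning of each field.
#'
#' @param height,width image dimensions.
#' @param bgMean,fgMean class means, raw scale, `bgMean < fgMean`.
#' @param bgSigma,fgSigma Gaussian within-class standard deviations.
#' @param saltDensity,pepperDensity impulse probabilities in \[0, 0.5\].
#' @param grayzoneWidth half-width (pixels, per side of the boundary) of the
#'   linear intensity ramp between the class means.
#' @param shape `"disk"`, `"rectangle"` or `"blob"`.
#' @param seed integer seed driving all stochastic draws.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(height = 128, width = 128, bgMean = 60, fgMean = 180,
                        bgSigma = 15, fgSigma = 15,
                        saltDensity = 0, pepperDensity = 0,
                        grayzoneWidth = 0, shape = "disk", seed = 1) {
  new("FixtureSpec", height = as.integer(height), width = as.integer(width),
      bgMean = bgMean, fgMean = fgMean, bgSigma = bgSigma, fgSigma = fgSigma,
      saltDensity = saltDensity, pepperDensity = pepperDensity,
      grayzoneWidth = as.integer(grayzoneWidth), shape = shape,
      seed = as.integer(seed))
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  code
}

diskMask <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# Object support; blob consumes RNG draws (call inside withSeed).
makeShape <- function(spec) {
  h <- spec@height; w <- spec@width
  switch(spec@shape,
    disk = diskMask(h, w, (h + 1) / 2, (w + 1) / 2, 0.3 * min(h, w)),
    rectangle = {
      m <- matrix(FALSE, h, w)
      m[max(1, round(h / 4)):round(3 * h / 4),
        max(1, round(w / 4)):round(3 * w / 4)] <- TRUE
      m
    },
    blob = {
      m <- matrix(FALSE, h, w)
      for (i in 1:3) {
        cy <- stats::runif(1, 0.35 * h, 0.65 * h)
        cx <- stats::runif(1, 0.35 * w, 0.65 * w)
        r <- stats::runif(1, 0.12, 0.22) * min(h, w)
        m <- m | diskMask(h, w, cy, cx, r)
      }
      m
    })
}

# Chessboard distance from each pixel of `region` to its complement,
# computed by iterated 8-neighbor dilation and capped at maxd + 1.
chessDistanceToComplement <- function(region, maxd) {
  d <- matrix(Inf, nrow(region), ncol(region))
  cur <- !region
  d[cur] <- 0
  offs <- neighborOffsets()
  for (k in seq_len(maxd)) {
    dil <- cur
    for (i in seq_len(nrow(offs)))
      dil <- dil | shiftMatrix(cur, offs$dr[i], offs$dc[i], FALSE)
    d[dil & is.infinite(d)] <- k
    cur <- dil
  }
  d
}

#' Generate a synthetic bimodal image with known ground truth
#'
#' Builds the object support, assigns each pixel its class mean, optionally
#' ramps the means linearly across a "grayness" transition band around the
#' object boundary (ground truth unchanged), adds Gaussian within-class
#' noise, clips to \[0, 255\] and rounds, then applies salt (255) and pepper
#' (0) impulses independently per pixel at the stated densities. Bit-identical
#' output for a fixed spec; the caller's RNG state is left untouched.
#'
#' @param spec a [FixtureSpec-class].
#' @param invert flip intensities (`255 - I`) after generation, for
#'   dark-object imagery; the truth mask still marks the object.
#' @return list with `image` (a [GrayImage-class]) and `truth` (a
#'   [BinaryMask-class] marking the noiseless object support).
#' @examples
#' fx <- generateFixture(fixtureSpec(height = 32, width = 32, seed = 7))
#' fx$image
#' @export
generateFixture <- function(spec, invert = FALSE) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    h <- spec@height; w <- spec@width
    truth <- makeShape(spec)
    meanMap <- matrix(spec@bgMean, h, w)
    meanMap[truth] <- spec@fgMean
    gw <- spec@grayzoneWidth
    if (gw > 0L) {
      mid <- (spec@bgMean + spec@fgMean) / 2
      span <- (spec@fgMean - spec@bgMean) / 2
      dIn <- chessDistanceToComplement(truth, gw)    # object side
      dOut <- chessDistanceToComplement(!truth, gw)  # background side
      band <- truth & is.finite(dIn) & dIn <= gw
      meanMap[band] <- mid + span * dIn[band] / (gw + 1)
      band <- !truth & is.finite(dOut) & dOut <= gw
      meanMap[band] <- mid - span * dOut[band] / (gw + 1)
    }
    sigmaMap <- matrix(spec@bgSigma, h, w)
    sigmaMap[truth] <- spec@fgSigma
    px <- meanMap + stats::rnorm(h * w) * sigmaMap
    px <- round(pmin(pmax(px, 0), 255))
    u <- stats::runif(h * w)
    px[u < spec@pepperDensity] <- 0
    px[u > 1 - spec@saltDensity] <- 255
    if (invert) px <- 255 - px
    list(image = grayImage(matrix(as.integer(px), h, w)),
         truth = binaryMask(truth))
  })
}

#' The default estimator sweep grid (22 configurations)
#'
#' The grid of mean-estimation configurations used throughout: the classical
#' (arithmetic) mean, a lognormal comparison placeholder (flagged
#' unsupported), harmonic, geometric, contraharmonic with
#' Q in \{-3, -1, -0.5, 0, 0.1\}, and alpha-trim with
#' d/2 in \{10, 20, 30, 40, 50, 55, 60, 65, 70, 80, 90, 100, 110\}.
#'
#' @return list of 22 [EstimatorSpec-class] objects.
#' @examples
#' length(sweepGrid())
#' @export
sweepGrid <- function() {
  c(list(estimatorSpec("classical"),
         estimatorSpec("lognormal"),
         estimatorSpec("harmonic"),
         estimatorSpec("geometric")),
    lapply(c(-3, -1, -0.5, 0, 0.1),
           function(q) estimatorSpec("contraharmonic", order = q)),
    lapply(c(10, 20, 30, 40, 50, 55, 60, 65, 70, 80, 90, 100, 110),
           function(d) estimatorSpec("alpha_trim", halfTrim = d)))
}

#' Materialize a fixture set to disk
#'
#' Writes each fixture as a PNG pair (`<stem>.png` and `<stem>_gt.png`) plus
#' a JSON manifest of the generating parameters, so batch tools consume the
#' set exactly like real data.
#'
#' @param specs list of [FixtureSpec-class] objects.
#' @param dir output directory (created if absent).
#' @param stems optional character vector of file stems (default
#'   `fixture_001`, ...).
#' @return invisibly, a data.frame with columns `stem`, `image`, `truth`.
#' @export
writeFixtureSet <- function(specs, dir, stems = NULL) {
  if (is(specs, "FixtureSpec")) specs <- list(specs)
  if (is.null(stems)) stems <- sprintf("fixture_%03d", seq_along(specs))
  stopifnot(length(stems) == length(specs))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", length(specs))
  paths <- data.frame(stem = stems,
                      image = file.path(dir, paste0(stems, ".png")),
                      truth = file.path(dir, paste0(stems, "_gt.png")))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    fx <- generateFixture(s)
    writeImagePNG(fx$image, paths$image[i])
    writeMask(fx$truth, paths$truth[i])
    manifest[[i]] <- list(stem = stems[i], height = s@height, width = s@width,
                          bg_mean = s@bgMean, fg_mean = s@fgMean,
                          bg_sigma = s@bgSigma, fg_sigma = s@fgSigma,
                          salt_density = s@saltDensity,
                          pepper_density = s@pepperDensity,
                          grayzone_width = s@grayzoneWidth,
                          shape = s@shape, seed = s@seed)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
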