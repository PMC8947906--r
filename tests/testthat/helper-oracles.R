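# Shared generators and independent reference implementations.
#
# The reference (oracle) code below works on per-pixel multisets with plain
# base-R arithmetic and exhaustive loops; the package works on count-weighted
# histogram forms. Keeping the two routes separate is the point: agreement is
# evidence, not tautology.

# Random raw pixel vectors with mixed histogram shapes.
randomPixels <- function(seed, n = 1500) {
  set.seed(seed)
  kind <- sample(c("spikes", "uniform", "bimodal"), 1)
  px <- switch(kind,
    spikes = {
      k <- sample(2:5, 1)
      levels <- sort(sample(0:255, k))
      sample(levels, n, replace = TRUE, prob = runif(k, 0.2, 1))
    },
    uniform = {
      lo <- sample(0:100, 1); hi <- sample(150:255, 1)
      sample(lo:hi, n, replace = TRUE)
    },
    bimodal = {
      m1 <- runif(1, 30, 90); m2 <- runif(1, 150, 220)
      s <- runif(1, 5, 25)
      v <- c(rnorm(n %/% 2, m1, s), rnorm(n - n %/% 2, m2, s))
      pmin(pmax(round(v), 0), 255)
    })
  as.integer(px)
}

randomImage <- function(seed, n = 1600) {
  px <- randomPixels(seed, n)
  side <- floor(sqrt(n))
  grayImage(matrix(px[seq_len(side * side)], side, side))
}

# Mode-vector mean, straight from the defining formulas on the sorted
# per-pixel vector. spec: list(method=, param=).
refMean <- function(v, method, param = NULL) {
  if (length(v) == 0) stop("empty")
  switch(method,
    classical = mean(v),
    harmonic = 1 / mean(1 / v),
    geometric = exp(mean(log(v))),
    contraharmonic = {
      out <- sum(v^(param + 1)) / sum(v^param)
      if (!is.finite(out)) stop("unstable")
      out
    },
    alpha_trim = {
      s <- sort(v)
      n <- length(s)
      if (n - 2 * param < 1) stop("trim too large")
      mean(s[(param + 1):(n - param)])
    })
}

# Exhaustive argmin of the cross-entropy objective over all candidate
# thresholds, on the per-pixel multiset of shifted levels. Returns the
# shifted threshold, or NA when no candidate is feasible.
refFindThreshold <- function(pxRaw, method, param = NULL) {
  lv <- sort(pxRaw + 1L)
  bestT <- NA_integer_
  bestVal <- Inf
  for (t in 1:255) {
    m1 <- lv[lv <= t]
    m2 <- lv[lv > t]
    if (length(m1) == 0L || length(m2) == 0L) next
    mu <- tryCatch(c(refMean(m1, method, param), refMean(m2, method, param)),
                   error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) next
    val <- -sum(m1) * log(mu[1]) - sum(m2) * log(mu[2])
    if (val < bestVal) {
      bestVal <- val
      bestT <- t
    }
  }
  bestT
}

# Per-pixel exhaustive inter-region disparity (8-neighborhood), looping over
# every pixel and neighbor explicitly.
refIRD <- function(I, M) {
  h <- nrow(I); w <- ncol(I)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  score <- function(region) {
    idx <- which(region, arr.ind = TRUE)
    ciSum <- 0; ceSum <- 0; border <- 0L
    for (r in seq_len(nrow(idx))) {
      y <- idx[r, 1]; x <- idx[r, 2]
      mIn <- -Inf; mOut <- -Inf
      hasIn <- FALSE; hasOut <- FALSE
      for (k in 1:8) {
        yy <- y + offs[k, 1]; xx <- x + offs[k, 2]
        if (yy < 1 || yy > h || xx < 1 || xx > w) next
        cc <- abs(I[y, x] - I[yy, xx]) / 255
        if (region[yy, xx]) { mIn <- max(mIn, cc); hasIn <- TRUE }
        else { mOut <- max(mOut, cc); hasOut <- TRUE }
      }
      ciSum <- ciSum + if (hasIn) mIn else 0
      if (hasOut) { border <- border + 1L; ceSum <- ceSum + mOut }
    }
    A <- nrow(idx)
    ci <- ciSum / A
    ce <- ceSum / border
    cr <- if (ci == 0) ce else if (ci < ce) 1 - ci / ce else 0
    c(cr, A)
  }
  s1 <- score(!M); s2 <- score(M)
  (s1[1] * s1[2] + s2[1] * s2[2]) / (s1[2] + s2[2])
}

# The 21 implementable grid configurations as (method, param) pairs.
implementableGrid <- function() {
  grid <- Filter(function(s) estimatorMethod(s) != "lognormal", sweepGrid())
  lapply(grid, function(s) list(method = estimatorMethod(s),
                                param = estimatorParam(s), spec = s))
}

twoSpikeImage <- function(nLow = 50, nHigh = 50, low = 10L, high = 200L) {
  grayImage(matrix(c(rep(low, nLow), rep(high, nHigh)), 1, nLow + nHigh))
}
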