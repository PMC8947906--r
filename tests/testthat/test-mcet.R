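test_that("mcetObjective matches its closed form", {
  img <- twoSpikeImage(nLow = 2, nHigh = 3, low = 9L, high = 199L)
  h <- computeHistogram(img)
  # unit means zero the log terms
  expect_equal(mcetObjective(h, 100, 1, 1), 0)
  expect_equal(mcetObjective(h, 100, 10, 200),
               -2 * 10 * log(10) - 3 * 200 * log(200))
  # doubling every count doubles n(t) at fixed means
  img2 <- twoSpikeImage(nLow = 4, nHigh = 6, low = 9L, high = 199L)
  h2 <- computeHistogram(img2)
  expect_equal(mcetObjective(h2, 100, 10, 200),
               2 * mcetObjective(h, 100, 10, 200))
  expect_error(mcetObjective(h, 100, 0, 5), "positive")
})

test_that("findThreshold separates a two-spike histogram and matches brute force", {
  img <- twoSpikeImage(nLow = 50, nHigh = 50, low = 9L, high = 199L)
  h <- computeHistogram(img)
  res <- findThreshold(h, estimatorSpec("classical"))
  expect_gte(thresholdShifted(res), 10)
  expect_lt(thresholdShifted(res), 200)
  expect_equal(thresholdShifted(res),
               refFindThreshold(as.vector(pixels(img)), "classical"))
  # the profile attains its minimum at the reported threshold
  prof <- objectiveProfile(res)
  expect_equal(which.min(prof), as.integer(thresholdShifted(res)))
  expect_true(all(prof[!is.na(prof)] >= prof[thresholdShifted(res)]))
})

test_that("findThreshold agrees with exhaustive search on a bimodal Gaussian histogram", {
  set.seed(99)
  px <- pmin(pmax(round(c(rnorm(5000, 60, 15), rnorm(5000, 180, 15))), 0), 255)
  img <- grayImage(matrix(as.integer(px), 100, 100))
  h <- computeHistogram(img)
  for (g in list(list(method = "classical", param = NULL),
                 list(method = "harmonic", param = NULL),
                 list(method = "geometric", param = NULL),
                 list(method = "contraharmonic", param = -0.5),
                 list(method = "alpha_trim", param = 50))) {
    spec <- switch(g$method,
                   alpha_trim = estimatorSpec("alpha_trim", halfTrim = g$param),
                   contraharmonic = estimatorSpec("contraharmonic", order = g$param),
                   estimatorSpec(g$method))
    expect_equal(thresholdShifted(findThreshold(h, spec)),
                 refFindThreshold(as.integer(px), g$method, g$param),
                 info = g$method)
  }
})

test_that("reduction identities propagate to identical ThresholdResults", {
  set.seed(12)
  img <- randomImage(12)
  h <- computeHistogram(img)
  classical <- findThreshold(h, estimatorSpec("classical"))
  q0 <- findThreshold(h, estimatorSpec("contraharmonic", order = 0))
  d0 <- findThreshold(h, estimatorSpec("alpha_trim", halfTrim = 0))
  harm <- findThreshold(h, estimatorSpec("harmonic"))
  qm1 <- findThreshold(h, estimatorSpec("contraharmonic", order = -1))
  expect_identical(thresholdRaw(q0), thresholdRaw(classical))
  expect_identical(thresholdRaw(d0), thresholdRaw(classical))
  expect_identical(thresholdRaw(qm1), thresholdRaw(harm))
  expect_equal(classMeans(q0), classMeans(classical), tolerance = 1e-9)
  expect_equal(classMeans(d0), classMeans(classical), tolerance = 1e-9)
  expect_equal(classMeans(qm1), classMeans(harm), tolerance = 1e-9)
})

test_that("degenerate and infeasible inputs are rejected with clear errors", {
  expect_error(findThreshold(computeHistogram(grayImage(matrix(5L, 3, 3))),
                             estimatorSpec("classical")),
               "degenerate histogram")
  expect_error(segmentImage(grayImage(matrix(5L, 3, 3)),
                            estimatorSpec("classical")),
               "degenerate histogram")
  # trim larger than any achievable class
  img <- twoSpikeImage(nLow = 5, nHigh = 5)
  expect_error(findThreshold(computeHistogram(img),
                             estimatorSpec("alpha_trim", halfTrim = 100)),
               "no feasible threshold")
  expect_error(findThreshold(computeHistogram(img), estimatorSpec("lognormal")),
               "unsupported")
})

test_that("segment of a perfectly separable image recovers the exact partition", {
  img <- grayImage(matrix(c(rep(10L, 32), rep(200L, 32)), 8, 8))
  expected <- matrix(as.integer(pixels(img) == 200L), 8, 8)
  for (s in list(estimatorSpec("classical"),
                 estimatorSpec("contraharmonic", order = 0),
                 estimatorSpec("alpha_trim", halfTrim = 0),
                 estimatorSpec("harmonic"),
                 estimatorSpec("geometric"))) {
    seg <- segmentImage(img, s)
    expect_identical(pixels(seg$mask), expected,
                     info = formatEstimatorSpec(s))
  }
})

test_that("adding a constant to a separable two-spike image shifts the threshold by it", {
  base <- twoSpikeImage(nLow = 40, nHigh = 60, low = 20L, high = 180L)
  t0 <- thresholdRaw(findThreshold(computeHistogram(base),
                                   estimatorSpec("classical")))
  for (cshift in c(10L, 25L, 50L)) {
    shifted <- grayImage(pixels(base) + cshift)
    t1 <- thresholdRaw(findThreshold(computeHistogram(shifted),
                                     estimatorSpec("classical")))
    expect_equal(t1, t0 + cshift)
  }
})

test_that("the alpha-trim threshold is more stable under impulse noise than the classical one", {
  # estimator-consistent robustness: compare each estimator's noisy threshold
  # with ITS OWN clean-image threshold, averaged over seeded replicates
  devClassical <- devTrim <- numeric(50)
  for (i in 1:50) {
    clean <- generateFixture(fixtureSpec(seed = 3000 + i))
    noisy <- generateFixture(fixtureSpec(saltDensity = 0.03,
                                         pepperDensity = 0.03,
                                         seed = 3000 + i))
    hC <- computeHistogram(clean$image)
    hN <- computeHistogram(noisy$image)
    trim <- estimatorSpec("alpha_trim", halfTrim = 50)
    devClassical[i] <- abs(
      thresholdRaw(findThreshold(hN, estimatorSpec("classical"))) -
        thresholdRaw(findThreshold(hC, estimatorSpec("classical"))))
    devTrim[i] <- abs(thresholdRaw(findThreshold(hN, trim)) -
                        thresholdRaw(findThreshold(hC, trim)))
  }
  expect_lte(mean(devTrim), mean(devClassical))
})

test_that("ThresholdResult serializes to JSON with threshold, means and spec", {
  seg <- segmentImage(twoSpikeImage(), estimatorSpec("alpha_trim", halfTrim = 5))
  js <- jsonlite::fromJSON(thresholdResultJSON(seg$result))
  expect_equal(js$t_raw, thresholdRaw(seg$result))
  expect_equal(js$estimator, "alpha_trim:5")
  expect_equal(js$mu1, unname(classMeans(seg$result)[1]))
  expect_length(js$objective, 255)
})
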