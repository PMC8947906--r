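test_that("classical mean is the arithmetic mean of the mode", {
  expect_equal(classicalMean(c(2, 2, 4, 4)), 3)
  expect_equal(classicalMean(7), 7)
  expect_equal(classicalMean(c(1, 2, 3, 4, 5, 100)), 115 / 6)
  expect_error(classicalMean(numeric(0)), "empty class")
})

test_that("alpha-trimmed mean drops halfTrim pixels per end, divisor length - d", {
  expect_equal(alphaTrimmedMean(c(1, 2, 3, 4, 5, 100), 1), 3.5)
  expect_equal(alphaTrimmedMean(c(10, 10, 10), 1), 10)
  expect_error(alphaTrimmedMean(c(1, 2), 1), "trim exceeds class size")
  expect_error(alphaTrimmedMean(c(1, 2, 3), 1.5), "non-negative integer")
  expect_error(alphaTrimmedMean(c(1, 2, 3), -1), "non-negative integer")
  # positional trimming on the sorted multiset, duplicates and all
  expect_equal(alphaTrimmedMean(c(5, 5, 5, 5, 9), 1), mean(c(5, 5, 5)))
})

test_that("harmonic and geometric means match their closed forms", {
  expect_equal(harmonicMean(c(1, 2, 4)), 12 / 7)
  expect_equal(harmonicMean(c(2, 8)), 3.2)
  expect_equal(harmonicMean(rep(17, 9)), 17)
  expect_equal(geometricMean(c(2, 8)), 4)
  expect_equal(geometricMean(c(1, 1, 8)), 2)
  expect_equal(geometricMean(rep(41, 5)), 41)
})

test_that("contraharmonic mean matches its closed form and error modes", {
  expect_equal(contraharmonicMean(c(1, 2, 3), 1), 14 / 6)
  expect_error(contraharmonicMean(numeric(0), 1), "empty class")
  expect_error(contraharmonicMean(c(1, 2), Inf), "finite")
  expect_error(contraharmonicMean(c(200, 250), 600), "unstable order")
})

test_that("reduction identities hold on 100 random modes (Q=0, Q=-1, d/2=0)", {
  set.seed(11)
  for (i in 1:100) {
    v <- sample(1:256, sample(3:60, 1), replace = TRUE)
    expect_equal(contraharmonicMean(v, 0), classicalMean(v), tolerance = 1e-9)
    expect_equal(contraharmonicMean(v, -1), harmonicMean(v), tolerance = 1e-9)
    expect_equal(alphaTrimmedMean(v, 0), classicalMean(v), tolerance = 1e-9)
  }
})

test_that("harmonic < geometric < arithmetic on non-constant modes, equal when constant", {
  set.seed(21)
  for (i in 1:200) {
    v <- sample(1:256, sample(2:50, 1), replace = TRUE)
    h <- harmonicMean(v); g <- geometricMean(v); a <- classicalMean(v)
    if (length(unique(v)) == 1L) {
      expect_equal(h, a); expect_equal(g, a)
    } else {
      expect_lt(h, g)
      expect_lt(g, a)
    }
  }
})

test_that("contraharmonic mean is strictly increasing in Q on non-constant modes", {
  set.seed(31)
  qs <- c(-3, -1, -0.5, 0, 0.1, 1)
  for (i in 1:50) {
    v <- sample(1:256, sample(2:40, 1), replace = TRUE)
    if (length(unique(v)) == 1L) next
    vals <- vapply(qs, function(q) contraharmonicMean(v, q), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("location bounds: means lie within [min, max] of the mode", {
  set.seed(41)
  for (i in 1:50) {
    v <- sample(1:256, sample(2:40, 1), replace = TRUE)
    for (m in list(classicalMean(v), harmonicMean(v), geometricMean(v),
                   alphaTrimmedMean(v, min(2, (length(v) - 1) %/% 2)))) {
      expect_gte(m, min(v)); expect_lte(m, max(v))
    }
  }
})

test_that("trimming is more robust to appended outliers than the classical mean", {
  set.seed(51)
  wins <- 0L
  for (i in 1:50) {
    v <- sample(40:120, 30, replace = TRUE)
    base <- classicalMean(v)
    k <- sample(1:3, 1)
    contaminated <- c(v, rep(max(v) + 100, k))
    devTrim <- abs(alphaTrimmedMean(contaminated, 3) - base)
    devClass <- abs(classicalMean(contaminated) - base)
    if (devTrim <= devClass) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("estimateMeans applies the same filter to both modes, matching the vector forms", {
  set.seed(61)
  grid <- implementableGrid()
  for (i in 1:10) {
    img <- randomImage(i + 400)
    h <- computeHistogram(img)
    for (t in c(80, 128, 180)) {
      m <- splitModes(h, t)
      if (length(m$mode1) < 250 || length(m$mode2) < 250) next
      for (g in grid) {
        mu <- estimateMeans(h, t, g$spec)
        expect_equal(unname(mu[1]), refMean(m$mode1, g$method, g$param),
                     tolerance = 1e-10)
        expect_equal(unname(mu[2]), refMean(m$mode2, g$method, g$param),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("estimateMeans on a two-spike histogram collapses to the spike levels", {
  img <- twoSpikeImage(low = 9L, high = 199L)  # shifted levels 10 / 200
  h <- computeHistogram(img)
  expect_equal(estimateMeans(h, 100, estimatorSpec("classical")),
               c(mu1 = 10, mu2 = 200))
  expect_equal(estimateMeans(h, 100, estimatorSpec("contraharmonic", order = 0)),
               c(mu1 = 10, mu2 = 200), tolerance = 1e-12)
  expect_equal(estimateMeans(h, 100, estimatorSpec("alpha_trim", halfTrim = 0)),
               c(mu1 = 10, mu2 = 200))
})

test_that("estimator spec grammar parses and round-trips; invalid strings rejected", {
  s <- parseEstimatorSpec("contraharmonic:-0.5")
  expect_equal(estimatorMethod(s), "contraharmonic")
  expect_equal(estimatorParam(s), -0.5)
  expect_equal(formatEstimatorSpec(s), "contraharmonic:-0.5")
  expect_equal(formatEstimatorSpec(parseEstimatorSpec("alpha_trim:55")),
               "alpha_trim:55")
  expect_equal(estimatorParam(parseEstimatorSpec("classical")), NA_real_)
  expect_error(parseEstimatorSpec("alpha_trim:-3"), "non-negative")
  expect_error(parseEstimatorSpec("alpha_trim"), "requires a parameter")
  expect_error(parseEstimatorSpec("classical:3"), "no parameter")
  expect_error(parseEstimatorSpec("mystery"), "unknown estimator")
  expect_error(parseEstimatorSpec("alpha_trim:abc"), "non-numeric")
  expect_error(estimatorSpec("alpha_trim", halfTrim = 2.5), "non-negative integer")
})
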