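test_that("pairedCompare reproduces the worked example and edge cases", {
  eq <- pairedCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statisticT, 0)
  expect_equal(eq$pValue, 1)

  dg <- pairedCompare(c(1, 5, 9), c(3, 7, 11))
  expect_true(dg$degenerate)
  expect_equal(dg$pValue, 0)

  fx <- pairedCompare(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(fx$statisticT, -5.196152, tolerance = 1e-6)
  expect_equal(fx$pValue, 0.013847, tolerance = 1e-4)
  expect_equal(fx$meanDiff, -1.5)

  expect_error(pairedCompare(1:4, 1:5), "equal length")
  expect_error(pairedCompare(1:2, 2:3), "at least 3")
})

test_that("F equals t squared on random paired draws", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.3)
    r <- pairedCompare(a, b)
    expect_equal(r$statisticF, r$statisticT^2, tolerance = 1e-9)
  }
})

test_that("pearsonCor handles exact, hand-computed, and degenerate input", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(pearsonCor(x, x)$r, 1)
  expect_equal(pearsonCor(x, -2 * x + 7)$r, -1)
  expect_equal(pearsonCor(c(1, 2, 3), c(1, 2, 4))$r, 0.981, tolerance = 1e-3)
  expect_equal(pearsonCor(x, 2 * x)$r, pearsonCor(2 * x, x)$r)
  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  set.seed(62)
  for (i in 1:20)
    expect_lte(abs(pearsonCor(rnorm(5), rnorm(5))$r), 1)
})

test_that("blandAltman matches hand arithmetic and mirrors", {
  same <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$meanDiff, 0)
  expect_equal(c(same$loaLow, same$loaHigh), c(0, 0))

  ba <- blandAltman(c(2, 1), c(1, 2))   # diffs +1, -1
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$sdDiff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loaHigh, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loaLow, -1.96 * sqrt(2), tolerance = 1e-12)

  a <- c(3, 6, 8); b <- a + 5
  off <- blandAltman(a, b)
  expect_equal(off$meanDiff, -5)
  expect_equal(off$sdDiff, 0)
  expect_equal(c(off$loaLow, off$loaHigh), c(-5, -5))

  set.seed(63)
  x <- rnorm(8); y <- rnorm(8)
  f <- blandAltman(x, y); g <- blandAltman(y, x)
  expect_equal(f$meanDiff, -g$meanDiff)
  expect_equal(f$loaLow, -g$loaHigh)
  expect_equal(f$loaHigh, -g$loaLow)
})

test_that("meanSD summarizes with the n-1 denominator", {
  expect_equal(meanSD(c(1, 1, 1)), c(mean = 1, sd = 0))
  expect_equal(meanSD(c(2, 4)), c(mean = 3, sd = sqrt(2)), tolerance = 1e-12)
  set.seed(64)
  v <- rnorm(10)
  expect_equal(meanSD(v), meanSD(sample(v)))
  expect_error(meanSD(1), "at least 2")
})
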