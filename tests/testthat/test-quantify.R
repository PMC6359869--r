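test_that("densityPercent is the foreground percentage", {
  expect_equal(densityPercent(binaryMask(matrix(FALSE, 10, 10))), 0)
  expect_equal(densityPercent(binaryMask(matrix(TRUE, 10, 10))), 100)
  m <- matrix(FALSE, 100, 100); m[seq_len(331)] <- TRUE
  expect_equal(densityPercent(binaryMask(m)), 3.31)
})

test_that("boxSizeSchedule produces strictly decreasing integer sizes", {
  s <- boxSizeSchedule(boxCountConfig(104, 15))
  expect_length(s, 15)
  expect_equal(s[1], 104)
  expect_gte(s[15], 2)
  expect_true(all(diff(s) < 0))

  expect_equal(boxSizeSchedule(boxCountConfig(8, 3)), c(8L, 4L, 2L))
  expect_error(boxCountConfig(104, 1), ">= 3")
})

test_that("boxCount matches closed forms for full masks and lines", {
  full <- binaryMask(matrix(TRUE, 768, 768))
  bf <- boxCount(full, boxCountConfig(104, 15))
  expect_equal(boxCounts(bf), ceiling(768 / boxSizes(bf))^2)
  expect_equal(dbox(bf), 2, tolerance = 0.02)

  ln <- matrix(FALSE, 768, 768); ln[384, ] <- TRUE
  bl <- boxCount(binaryMask(ln), boxCountConfig(104, 15))
  expect_equal(boxCounts(bl), ceiling(768 / boxSizes(bl)))
  expect_equal(dbox(bl), 1, tolerance = 0.05)

  expect_error(boxCount(binaryMask(matrix(FALSE, 200, 200))), "empty mask")
  expect_error(boxCount(binaryMask(matrix(TRUE, 50, 50)),
                        boxCountConfig(104, 15)), "too small")
})

test_that("boxCount equals the naive scanner and counts are monotone", {
  set.seed(51)
  for (i in 1:6) {
    m <- matrix(runif(100 * 90) < 0.06, 100, 90)
    if (!any(m)) next
    bc <- boxCount(binaryMask(m), boxCountConfig(24, 6))
    for (j in seq_along(boxSizes(bc)))
      expect_equal(boxCounts(bc)[j], naiveBoxCount(m, boxSizes(bc)[j]))
    expect_true(all(diff(boxCounts(bc)) >= 0))   # sizes descend, N grows
  }
})

test_that("quantifySkeleton is deterministic and monotone under nesting", {
  net <- generateNetwork(syntheticConfig(seed = 6, nRoots = 12L))
  sk <- groundTruthSkeleton(net, c(256L, 256L), c(10, 10))
  r1 <- quantifySkeleton(sk, boxCountConfig(104, 15), subject = 1,
                         eye = "OD", modality = "octa_like")
  r2 <- quantifySkeleton(sk, boxCountConfig(104, 15), subject = 1,
                         eye = "OD", modality = "octa_like")
  expect_identical(r1, r2)
  expect_named(r1, c("subject", "eye", "modality", "density_percent",
                     "dbox", "r_squared"))

  a <- maskPixels(sk)
  b <- a
  drop <- which(a)
  b[drop[seq_len(length(drop) %/% 3)]] <- FALSE  # delete a third of A
  expect_true(any(b))
  qa <- quantifySkeleton(binaryMask(a), boxCountConfig(104, 15))
  qb <- quantifySkeleton(binaryMask(b), boxCountConfig(104, 15))
  expect_gt(qa$density_percent, qb$density_percent)
  expect_gte(qa$dbox, qb$dbox - 0.02)
})

test_that("percent and Dbox are strongly associated across graded networks", {
  pv <- dv <- numeric(0)
  for (i in 1:22) {
    net <- generateNetwork(syntheticConfig(seed = 100 + i,
                                           nRoots = 4L + 4L * i))
    sk <- groundTruthSkeleton(net, c(512L, 512L), c(10, 10))
    pv <- c(pv, densityPercent(sk))
    dv <- c(dv, dbox(boxCount(sk, boxCountConfig(104, 15))))
  }
  expect_gt(pearsonCor(pv, dv)$r, 0.9)
})
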