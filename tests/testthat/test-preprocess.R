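test_that("toGrayscale implements both conversion methods", {
  g <- array(0, c(8, 8, 3)); g[, , 2] <- 1
  img <- calibratedImage(g, c(1, 1), "fslb_like")
  expect_true(all(toGrayscale(img, "green")@pixels == 1))

  v <- array(0.42, c(8, 8, 3))
  achro <- calibratedImage(v, c(1, 1), "fslb_like")
  expect_equal(toGrayscale(achro, "green")@pixels,
               matrix(0.42, 8, 8), tolerance = 1e-12)
  expect_equal(round(toGrayscale(achro, "luminance")@pixels * 255),
               matrix(round(0.42 * 255), 8, 8))

  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 100 / 255; rgb[, , 2] <- 150 / 255; rgb[, , 3] <- 200 / 255
  lum <- toGrayscale(calibratedImage(rgb, c(1, 1), "fslb_like"), "luminance")
  expect_true(all(round(lum@pixels * 255) == 141))

  gray <- ci(matrix(0.5, 8, 8))
  expect_message(out <- toGrayscale(gray), "already grayscale")
  expect_identical(out@pixels, gray@pixels)
})

test_that("equalizeGlobal follows the cdf mapping", {
  m <- matrix(200 / 255, 16, 16)
  m[1:4, ] <- 50 / 255   # 25% at level 50, 75% at level 200
  eq <- equalizeGlobal(ci(m))
  lv <- round(eq@pixels * 255)
  expect_true(all(lv[1:4, ] == round(255 * 0.25)))
  expect_true(all(lv[5:16, ] == 255))

  const <- equalizeGlobal(ci(matrix(0.7, 8, 8)))
  expect_equal(length(unique(as.vector(const@pixels))), 1)

  # a uniformly distributed image is a fixed point up to 1 gray level
  u <- matrix(rep(0:255, each = 4) / 255, 32, 32)
  eu <- equalizeGlobal(ci(u))
  expect_lte(max(abs(round(eu@pixels * 255) - round(u * 255))), 1)
})

test_that("equalizeAdaptive degenerates to global and boosts local contrast", {
  set.seed(31)
  m <- matrix(runif(64 * 64), 64)
  img <- ci(m)
  expect_equal(equalizeAdaptive(img, tiles = 1, clipLimit = Inf)@pixels,
               equalizeGlobal(img)@pixels, tolerance = 1e-12)

  const <- equalizeAdaptive(ci(matrix(0.3, 32, 32)), 4, 0.05)
  expect_equal(length(unique(as.vector(const@pixels))), 1)

  set.seed(32)
  half <- matrix(0, 128, 128)
  half[, 1:64] <- pmin(pmax((150 + rnorm(128 * 64, 0, 20)) / 255, 0), 1)
  half[, 65:128] <- pmin(pmax((40 + rnorm(128 * 64, 0, 8)) / 255, 0), 1)
  gG <- equalizeGlobal(ci(half))
  gA <- equalizeAdaptive(ci(half), 4, 0.05)
  expect_gt(sd(gA@pixels[, 65:128]), sd(gG@pixels[, 65:128]))

  expect_error(equalizeAdaptive(ci(matrix(0.5, 4, 4)), tiles = 4), "tile")
})

test_that("removeBackground flattens background and keeps thin dark vessels", {
  const <- removeBackground(ci(matrix(0.6, 64, 64)), 5)
  expect_true(all(const@pixels == 0))

  ln <- matrix(200 / 255, 64, 64); ln[31:33, ] <- 50 / 255
  rb <- removeBackground(ci(ln), 5)
  expect_true(all(rb@pixels[31:33, 10:55] > 0))
  expect_true(all(rb@pixels[c(1:20, 45:64), ] == 0))

  dk <- matrix(200 / 255, 64, 64)
  for (r in 1:64) for (c in 1:64)
    if ((r - 32)^2 + (c - 32)^2 <= 400) dk[r, c] <- 50 / 255
  rbd <- removeBackground(ci(dk), 5)
  expect_lte(max(rbd@pixels[27:37, 27:37]), 1e-12)

  expect_error(removeBackground(ci(matrix(0.5, 20, 20)), 15), "radius")
})

test_that("preprocess operations preserve dims and FOV", {
  set.seed(33)
  img <- ci(matrix(runif(48 * 40), 40, 48), fov = c(4.8, 4.0))
  for (out in list(equalizeGlobal(img), equalizeAdaptive(img, 4, 0.02),
                   removeBackground(img, 6))) {
    expect_equal(dim(out@pixels), c(40L, 48L))
    expect_equal(out@fovMM, c(4.8, 4.0))
  }
})
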