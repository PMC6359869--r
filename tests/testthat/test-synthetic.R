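test_that("generateNetwork is deterministic and honors its config", {
  cfg <- syntheticConfig(seed = 7, nRoots = 6L, fovMM = c(6, 6))
  n1 <- generateNetwork(cfg)
  n2 <- generateNetwork(cfg)
  expect_identical(n1@segments, n2@segments)
  expect_identical(n1@widthsMM, n2@widthsMM)

  empty <- generateNetwork(syntheticConfig(seed = 1, nRoots = 0L))
  expect_length(networkSegments(empty), 0)

  expect_error(syntheticConfig(widthRangeMM = c(0, 0.1)), "widthRangeMM")
  expect_error(syntheticConfig(widthRangeMM = c(0.05, 0.5)), "widthRangeMM")
})

test_that("network vertices stay inside the FOV and widths are positive", {
  net <- generateNetwork(syntheticConfig(seed = 2, nRoots = 10L,
                                         fovMM = c(5, 4)))
  for (seg in networkSegments(net)) {
    expect_true(all(seg[, 1] >= 0 & seg[, 1] <= 5))
    expect_true(all(seg[, 2] >= 0 & seg[, 2] <= 4))
  }
  expect_true(all(networkWidths(net) > 0))
})

test_that("doubling nRoots increases mean total centerline length", {
  lenAt <- function(nr) {
    mean(vapply(1:20, function(s)
      totalLengthMM(generateNetwork(
        syntheticConfig(seed = 300 + s, nRoots = nr))), numeric(1)))
  }
  expect_gt(lenAt(20L), lenAt(10L))
})

test_that("renderModality handles empty and single-vessel networks", {
  empty <- generateNetwork(syntheticConfig(seed = 1, nRoots = 0L))
  p0 <- modalityParams("octa_like", nativeGrid = c(64L, 64L),
                       fovMM = c(15.74, 10.5), noiseLevel = 0,
                       backgroundLevel = 0, flowFloor = 0)
  img <- renderModality(empty, p0, seed = 1)
  expect_true(all(img@pixels == 0))

  net <- singleVesselNet()
  p1 <- modalityParams("octa_like", nativeGrid = c(128L, 128L),
                       noiseLevel = 0)
  v <- renderModality(net, p1, seed = 1)
  prof <- rowMeans(v@pixels)
  # vessel at y = 4.4 mm -> row index 4.4 / (8.775 / 128) + 0.5 ~ 64.7
  expect_lte(abs(which.max(prof) - 64.7), 1.5)
  # unimodal: profile rises to the peak then falls
  pk <- which.max(prof)
  expect_true(all(diff(prof[1:pk]) >= -1e-12))
  expect_true(all(diff(prof[pk:length(prof)]) <= 1e-12))
})

test_that("renderModality is deterministic given (net, params, seed)", {
  net <- generateNetwork(syntheticConfig(seed = 4, nRoots = 4L))
  p <- modalityParams("octa_like", nativeGrid = c(96L, 96L))
  expect_identical(renderModality(net, p, seed = 5)@pixels,
                   renderModality(net, p, seed = 5)@pixels)
})

test_that("flowFloor blanks sub-threshold background", {
  net <- singleVesselNet(widthMM = 0.1)
  p <- modalityParams("octa_like", nativeGrid = c(128L, 128L),
                      noiseLevel = 0)
  img <- renderModality(net, p, seed = 1)
  # background (top rows, far from the vessel) displays as exactly 0
  expect_true(all(img@pixels[1:20, ] == 0))
  expect_gt(max(img@pixels), 0.5)
})

test_that("minDetectableMM suppresses thinner vessels entirely", {
  net <- singleVesselNet(widthMM = 0.02)
  p <- modalityParams("octa_like", nativeGrid = c(128L, 128L),
                      noiseLevel = 0, backgroundLevel = 0, flowFloor = 0,
                      minDetectableMM = 0.05)
  expect_true(all(renderModality(net, p, seed = 1)@pixels == 0))
})

test_that("groundTruthSkeleton rasterizes centerlines as expected", {
  empty <- generateNetwork(syntheticConfig(seed = 1, nRoots = 0L))
  expect_equal(sum(maskPixels(
    groundTruthSkeleton(empty, c(50L, 50L), c(5, 5)))), 0)

  span <- new("GroundTruthNetwork",
              segments = list(cbind(c(0, 10), c(5, 5))),
              widthsMM = 0.05, fovMM = c(10, 10))
  sk <- groundTruthSkeleton(span, c(100L, 100L), c(10, 10))
  expect_gte(sum(maskPixels(sk)), 98)
  expect_lte(sum(maskPixels(sk)), 102)
})

test_that("truth-skeleton density grows with nRoots", {
  densAt <- function(nr) {
    mean(vapply(1:20, function(s) {
      net <- generateNetwork(syntheticConfig(seed = 400 + s, nRoots = nr))
      densityPercent(groundTruthSkeleton(net, c(128L, 128L), c(10, 10)))
    }, numeric(1)))
  }
  d <- vapply(c(5L, 15L, 30L), densAt, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("truth-skeleton density scales inversely with linear grid size", {
  net <- generateNetwork(syntheticConfig(seed = 12, nRoots = 15L))
  d1 <- densityPercent(groundTruthSkeleton(net, c(128L, 128L), c(10, 10)))
  d2 <- densityPercent(groundTruthSkeleton(net, c(256L, 256L), c(10, 10)))
  # a 1-px curve occupies ~length/pitch pixels: density ratio ~ grid ratio
  expect_gt(d1 / d2, 2 * 0.8)
  expect_lt(d1 / d2, 2 * 1.2)
})
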