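# Shared fixtures and independent oracles used across the suite. Everything
# here is deliberately naive (double loops, brute-force scans) so that the
# package implementations are checked against code with no shared logic.

ci <- function(m, fov = c(1, 1), mod = "octa_like") {
  calibratedImage(m, fovMM = fov, modality = mod)
}

# Naive occupied-box counter: double loop over a top-left-anchored grid,
# partial edge boxes included.
naiveBoxCount <- function(m, s) {
  n <- 0L
  for (r0 in seq(1L, nrow(m), by = s)) {
    for (c0 in seq(1L, ncol(m), by = s)) {
      if (any(m[r0:min(nrow(m), r0 + s - 1L), c0:min(ncol(m), c0 + s - 1L)]))
        n <- n + 1L
    }
  }
  n
}

# Brute-force Otsu: scan all 256 thresholds, between-class variance
# w0 * w1 * (mu0 - mu1)^2 with class 0 = levels <= t; return the lowest
# maximizing level. `lv` is an integer vector of 0..255 levels.
bruteOtsu <- function(lv) {
  h <- tabulate(lv + 1L, nbins = 256L)
  p <- h / sum(h)
  best <- -Inf; bestT <- NA_integer_
  for (t in 0:255) {
    w0 <- sum(p[1:(t + 1L)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1L)] * (0:t)) / w0
    mu1 <- sum(p[(t + 2L):256L] * ((t + 1L):255L)) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; bestT <- t }
  }
  bestT
}

# Sierpinski carpet raster with 3^depth px per side (depth 5 -> 243 x 243).
sierpinskiCarpet <- function(depth) {
  m <- matrix(TRUE, 3, 3); m[2, 2] <- FALSE
  for (i in seq_len(depth - 1L)) {
    n <- nrow(m)
    big <- matrix(FALSE, 3L * n, 3L * n)
    for (r in 0:2) for (c in 0:2) {
      if (!(r == 1 && c == 1)) big[r * n + 1:n, c * n + 1:n] <- m
    }
    m <- big
  }
  m
}

# Random blob mask: union of a few axis-aligned rectangles and discs.
randomBlob <- function(n = 64L) {
  m <- matrix(FALSE, n, n)
  for (k in seq_len(sample(3:7, 1))) {
    if (runif(1) < 0.5) {
      r0 <- sample(n - 8L, 1); c0 <- sample(n - 8L, 1)
      m[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- TRUE
    } else {
      cr <- sample(5:(n - 5L), 2); rad <- sample(2:6, 1)
      for (r in max(1, cr[1] - rad):min(n, cr[1] + rad))
        for (c in max(1, cr[2] - rad):min(n, cr[2] + rad))
          if ((r - cr[1])^2 + (c - cr[2])^2 <= rad^2) m[r, c] <- TRUE
    }
  }
  m
}

# 8-connected component count via igraph, independent of package internals.
components8 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    okn <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    j <- (c2[okn] - 1L) * nr + r2[okn]
    hit <- pos[j] > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[idx[okn]][hit], pos[j][hit]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}

# Precision / recall of an extracted skeleton against a ground truth,
# each side dilated by `tol` px (Chebyshev) for the matching.
precisionRecall <- function(skel, truth, tol = 2L) {
  s <- skel@mask; t <- truth@mask
  grow <- function(m) {
    EBImage::dilate(EBImage::Image(m * 1),
                    EBImage::makeBrush(2L * tol + 1L, "box")) > 0
  }
  c(precision = sum(s & grow(t)) / sum(s),
    recall = sum(t & grow(s)) / sum(t))
}

# A single straight horizontal vessel spanning most of an 8.775 mm FOV.
singleVesselNet <- function(widthMM = 0.08, y = 4.4) {
  new("GroundTruthNetwork",
      segments = list(cbind(c(0.5, 8.2), c(y, y))),
      widthsMM = widthMM, fovMM = c(8.775, 8.775))
}

# Small, fast pipeline configuration for unit tests (identical structure to
# the default, smaller grids).
smallCfg <- function() pipelineConfig(workingPx = 256L,
                                      preResizeWidthPx = 512L)
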