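#' Gaussian blur
#'
#' Convolution with a normalized 2-D Gaussian kernel truncated at 4 sigma,
#' with symmetric (mirror) border padding. Used as the de-noising step ahead
#' of bandpass filtering and thresholding; the default sigma of 4 px is
#' expressed at the working analysis resolution.
#'
#' @param img a grayscale [CalibratedImage-class].
#' @param sigmaPx Gaussian standard deviation in pixels (> 0).
#' @return The blurred image (dims and FOV preserved).
#' @export
gaussianBlur <- function(img, sigmaPx = 4) {
  stopifnot(is(img, "CalibratedImage"))
  if (sigmaPx <= 0) stop("sigma must be positive")
  if (length(dim(img@pixels)) != 2L) stop("gaussianBlur expects grayscale")
  r <- ceiling(4 * sigmaPx)
  g <- stats::dnorm(-r:r, sd = sigmaPx)
  g <- g / sum(g)
  k <- outer(g, g)
  padded <- .padReflect(img@pixels, r)
  out <- as.matrix(EBImage::filter2(padded, k, boundary = "circular"))
  out <- out[(r + 1L):(r + nrow(img@pixels)),
             (r + 1L):(r + ncol(img@pixels)), drop = FALSE]
  calibratedImage(.clamp01(out), fovMM = img@fovMM, modality = img@modality)
}

# Mirror-pad a matrix to the next power of two per axis and return the
# padded matrix plus the crop window. Exposed internally so the bandpass
# padding-transparency property can be tested against explicit pre-tiling.
.padPow2 <- function(m) {
  N <- c(.nextPow2(nrow(m)), .nextPow2(ncol(m)))
  list(m = .padReflect(m, 0L, N[1L] - nrow(m), 0L, N[2L] - ncol(m)),
       rows = seq_len(nrow(m)), cols = seq_len(ncol(m)))
}

# Difference-of-Gaussians transfer function on an N1 x N2 frequency grid:
# each structure-size cutoff d (px) acts as a Gaussian low-pass with spatial
# sigma d/3 (amplitude ~0.11 at wavelength d).
.bandpassTransfer <- function(N1, N2, largePx, smallPx) {
  f1 <- c(0:(N1 %/% 2), -((N1 - N1 %/% 2 - 1L):1)) / N1
  f2 <- c(0:(N2 %/% 2), -((N2 - N2 %/% 2 - 1L):1)) / N2
  rho2 <- outer(f1^2, f2^2, "+")
  lp <- function(d) exp(-2 * pi^2 * (d / 3)^2 * rho2)
  lp(smallPx) - lp(largePx)
}

#' Frequency-domain bandpass filter
#'
#' Suppresses structures larger than `filterLargePx` and smaller than
#' `filterSmallPx` using a difference of Gaussian transfer functions in the
#' Fourier domain (each cutoff d acts as a Gaussian low-pass of spatial
#' sigma d/3). The image is mirror-padded to the next power of two before
#' the transform, so the filter sees a continuous periodic extension. With
#' `rescale = TRUE` (the "no saturation" convention) the output is linearly
#' mapped onto [0, 1] with no percentile clipping; a spectrally flat result
#' maps to a constant mid level of 0.5.
#'
#' @param img a grayscale [CalibratedImage-class].
#' @param filterLargePx,filterSmallPx structure-size cutoffs in pixels,
#'   large > small > 0.
#' @param rescale linearly stretch the result to [0, 1] (default TRUE); with
#'   FALSE the raw filtered values are returned (useful for measuring
#'   amplitude transfer).
#' @return The filtered [CalibratedImage-class].
#' @export
fftBandpass <- function(img, filterLargePx = 40, filterSmallPx = 3,
                        rescale = TRUE) {
  stopifnot(is(img, "CalibratedImage"))
  if (length(dim(img@pixels)) != 2L) stop("fftBandpass expects grayscale")
  if (filterLargePx <= filterSmallPx || filterSmallPx <= 0)
    stop("cutoffs must satisfy large > small > 0")
  pad <- .padPow2(img@pixels)
  H <- .bandpassTransfer(nrow(pad$m), ncol(pad$m), filterLargePx,
                         filterSmallPx)
  filt <- Re(stats::fft(stats::fft(pad$m) * H, inverse = TRUE)) /
    length(pad$m)
  out <- filt[pad$rows, pad$cols, drop = FALSE]
  if (rescale) {
    rng <- range(out)
    out <- if (rng[2L] - rng[1L] < 1e-12)
      matrix(0.5, nrow(out), ncol(out))
    else (out - rng[1L]) / (rng[2L] - rng[1L])
  }
  calibratedImage(out, fovMM = img@fovMM, modality = img@modality)
}

#' Otsu thresholding
#'
#' Binarizes a grayscale image at the 256-level threshold maximizing the
#' between-class variance of its histogram (the bimodal
#' foreground/background model). Foreground is strictly above the threshold;
#' among tied maximizers the lowest level is returned. A constant image has
#' no two classes to separate and raises a "degenerate histogram" error.
#'
#' @param img a grayscale [CalibratedImage-class] with at least two distinct
#'   levels.
#' @param provenance identifier stored in the mask.
#' @return A list with `level` (integer threshold on the 0..255 scale) and
#'   `mask` (a [BinaryMask-class] marking pixels above the threshold).
#' @export
otsuThreshold <- function(img, provenance = "") {
  stopifnot(is(img, "CalibratedImage"))
  if (length(dim(img@pixels)) != 2L) stop("otsuThreshold expects grayscale")
  lv <- .toLevels(img@pixels)
  h <- tabulate(lv + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) stop("degenerate histogram: image has a single level")
  n <- length(lv)
  p <- h / n
  levels <- 0:255
  w0 <- cumsum(p)                      # class 0: levels <= t
  mu <- cumsum(p * levels)
  muT <- mu[256L]
  w1 <- 1 - w0
  # between-class variance for thresholds t = 0..254
  bcv <- (muT * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  bcv <- bcv[1:255]
  level <- levels[which.max(bcv)]      # which.max takes the lowest maximizer
  mask <- lv > level
  list(level = level,
       mask = binaryMask(mask, provenance = provenance, threshold = level))
}

# --- Zhang-Suen thinning -----------------------------------------------

# Neighbor maps in the Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
# (row decreases upward; our row index grows downward so N = row - 1).
.zsNeighbors <- function(m) {
  list(
    p2 = .shiftMat(m,  1L,  0L),  # value of northern neighbor at each pixel
    p3 = .shiftMat(m,  1L, -1L),
    p4 = .shiftMat(m,  0L, -1L),
    p5 = .shiftMat(m, -1L, -1L),
    p6 = .shiftMat(m, -1L,  0L),
    p7 = .shiftMat(m, -1L,  1L),
    p8 = .shiftMat(m,  0L,  1L),
    p9 = .shiftMat(m,  1L,  1L))
}

# One parallel sub-iteration; returns the logical deletion map.
.zsSubIter <- function(m, second) {
  nb <- .zsNeighbors(m)
  B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
  seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  A <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1L]])
  if (!second) {
    c1 <- !(nb$p2 & nb$p4 & nb$p6)
    c2 <- !(nb$p4 & nb$p6 & nb$p8)
  } else {
    c1 <- !(nb$p2 & nb$p4 & nb$p8)
    c2 <- !(nb$p2 & nb$p6 & nb$p8)
  }
  m & B >= 2 & B <= 6 & A == 1L & c1 & c2
}

# Parallel deletion can erase a small component entirely (e.g. an isolated
# 2x2 square). Detect deletion clusters with no surviving neighbor — those
# are exactly whole vanished components — and retain one pixel of each.
.guardVanished <- function(m, del) {
  if (!any(del)) return(del)
  surv <- m & !del
  nearSurv <- surv
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) nearSurv <- nearSurv | .shiftMat(surv, dr, dc)
  orphan <- del & !nearSurv
  if (!any(orphan)) return(del)
  comp <- .components8(del)
  touched <- tapply(!orphan[comp$idx], comp$membership, any)
  for (cl in as.integer(names(touched))[!touched]) {
    keep <- comp$idx[comp$membership == cl][1L]
    del[keep] <- FALSE
  }
  del
}

# Number of 8-connected components among the 8 neighbors of a single pixel,
# given the 3x3 neighborhood nb (logical; the center cell is excluded).
# Adjacency is direct 8-adjacency between neighbor cells, never through the
# center, so the count tells whether deleting the center disconnects its
# neighborhood.
.localComponents <- function(nb) {
  cells <- which(nb & !(row(nb) == 2L & col(nb) == 2L))
  k <- length(cells)
  if (k == 0L) return(0L)
  r <- (cells - 1L) %% 3L; cc <- (cells - 1L) %/% 3L
  seen <- logical(k)
  n <- 0L
  for (i in seq_len(k)) {
    if (seen[i]) next
    n <- n + 1L
    queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      adj <- !seen & abs(r - r[cur]) <= 1L & abs(cc - cc[cur]) <= 1L
      seen[adj] <- TRUE
      queue <- c(queue, which(adj))
    }
  }
  n
}

# Remove residual 2x2 all-foreground blocks left by parallel thinning,
# deleting only pixels whose removal keeps the local neighborhood connected
# (connectivity number 1) and which are not endpoints.
.thinCleanup <- function(m) {
  repeat {
    if (nrow(m) < 2L || ncol(m) < 2L) break
    a <- m[-nrow(m), , drop = FALSE] & m[-1L, , drop = FALSE]
    blocks <- which(a[, -ncol(a), drop = FALSE] & a[, -1L, drop = FALSE],
                    arr.ind = TRUE)
    if (!nrow(blocks)) break
    for (b in seq_len(nrow(blocks))) {
      r <- blocks[b, 1L]; cc <- blocks[b, 2L]
      cand <- rbind(c(r, cc), c(r, cc + 1L), c(r + 1L, cc), c(r + 1L, cc + 1L))
      if (!all(m[cand])) next   # already resolved by an earlier deletion
      # order candidates by neighbor count, most-connected first
      counts <- apply(cand, 1L, function(p) {
        nb <- .neighborhood3(m, p[1L], p[2L]); sum(nb) - 1L
      })
      removed <- FALSE
      for (j in order(-counts)) {
        p <- cand[j, ]
        nb <- .neighborhood3(m, p[1L], p[2L])
        if (sum(nb) - 1L <= 1L) next            # endpoint: keep
        nb[2L, 2L] <- FALSE
        if (.localComponents(nb) == 1L) {
          m[p[1L], p[2L]] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (!removed) {
        # no safe pixel (theoretical corner case): remove the densest one
        j <- order(-counts)[1L]
        m[cand[j, 1L], cand[j, 2L]] <- FALSE
      }
    }
  }
  m
}

.neighborhood3 <- function(m, r, cc) {
  out <- matrix(FALSE, 3L, 3L)
  rs <- (r - 1L):(r + 1L); cs <- (cc - 1L):(cc + 1L)
  okr <- rs >= 1L & rs <= nrow(m); okc <- cs >= 1L & cs <= ncol(m)
  out[okr, okc] <- m[rs[okr], cs[okc], drop = FALSE]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels with the two-subiteration Zhang-Suen
#' scheme until stable, preserving 8-connectivity (a guard retains one pixel
#' of any small component that a parallel pass would erase entirely), then
#' clears residual 2x2 staircase blocks by connectivity-preserving deletion
#' so the result satisfies the thinness invariant of
#' [SkeletonMask-class].
#'
#' @param mask a [BinaryMask-class].
#' @return A [SkeletonMask-class]; a subset of the input mask with the same
#'   number of 8-connected components.
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@mask
  repeat {
    del <- .guardVanished(m, .zsSubIter(m, second = FALSE))
    m2 <- m & !del
    del <- .guardVanished(m2, .zsSubIter(m2, second = TRUE))
    m3 <- m2 & !del
    if (identical(m3, m)) break
    m <- m3
  }
  skeletonMask(.thinCleanup(m), provenance = mask@provenance)
}
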