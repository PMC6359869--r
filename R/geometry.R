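#' Resample a calibrated image to a new pixel grid
#'
#' Bilinear interpolation for intensity images; binary masks should instead
#' be resampled with `filter = "none"` (nearest neighbor) to preserve
#' binarity. Resizing changes the sampling, not the physical extent, so the
#' FOV in mm is unchanged and the mm-per-pixel pitch rescales accordingly.
#'
#' @param img a [CalibratedImage-class].
#' @param newWidthPx,newHeightPx target dimensions in pixels.
#' @param filter `"bilinear"` or `"none"` (nearest neighbor).
#' @return The resampled [CalibratedImage-class], same FOV.
#' @examples
#' img <- calibratedImage(matrix(runif(304^2), 304, 304), c(8.775, 8.775))
#' big <- resizeImage(img, 1024, 1024)
#' fovMM(big)   # unchanged: 8.775 x 8.775 mm
#' @export
resizeImage <- function(img, newWidthPx, newHeightPx,
                        filter = c("bilinear", "none")) {
  stopifnot(is(img, "CalibratedImage"))
  filter <- match.arg(filter)
  if (newWidthPx < 1 || newHeightPx < 1)
    stop("target dimensions must be positive")
  d <- dim(img@pixels)
  if (newWidthPx == d[2L] && newHeightPx == d[1L]) return(img)
  # EBImage treats dim 1 as x; our matrices are [row = y, col = x], so the
  # first EBImage extent is our height.
  rs <- function(m) EBImage::resize(m, w = newHeightPx, h = newWidthPx,
                                    filter = filter)
  px <- if (length(d) == 2L) rs(img@pixels) else {
    out <- array(0, c(newHeightPx, newWidthPx, 3L))
    for (ch in 1:3) out[, , ch] <- rs(img@pixels[, , ch])
    out
  }
  calibratedImage(.clamp01(as.array(px)), fovMM = img@fovMM,
                  modality = img@modality)
}

#' Resize preserving aspect ratio
#'
#' Convenience wrapper fixing the target width; the height follows from the
#' aspect ratio, rounded to the nearest pixel (5184 x 3456 at width 1024
#' gives 683).
#'
#' @param img a [CalibratedImage-class].
#' @param newWidthPx target width in pixels.
#' @param filter interpolation, as in [resizeImage()].
#' @return The resampled image.
#' @export
resizeToWidth <- function(img, newWidthPx, filter = "bilinear") {
  d <- dim(img@pixels)
  newHeightPx <- round(d[1L] * newWidthPx / d[2L])
  resizeImage(img, newWidthPx, newHeightPx, filter = filter)
}

#' Crop a calibrated image, shrinking its FOV accordingly
#'
#' Extracts a `cropWidthPx` x `cropHeightPx` window, centered by default or
#' displaced by `offset` (pixels, (dx, dy) from the centered position). The
#' new FOV is the old FOV scaled by the cropped fraction per axis (cropping
#' 768 px out of 1024 px spanning 8.775 mm leaves 6.58125 mm, reported as
#' 6.581 via [fovReport()]). Windows are half-open pixel ranges.
#'
#' @param img a [CalibratedImage-class].
#' @param cropWidthPx,cropHeightPx window size in pixels, at most the image
#'   size.
#' @param offset integer(2) optional (dx, dy) displacement of the window.
#' @return The cropped [CalibratedImage-class].
#' @examples
#' img <- calibratedImage(matrix(0.2, 1024, 1024), c(8.775, 8.775))
#' fovReport(centerCrop(img, 768, 768))   # 6.581 6.581
#' @export
centerCrop <- function(img, cropWidthPx, cropHeightPx, offset = c(0L, 0L)) {
  stopifnot(is(img, "CalibratedImage"))
  d <- dim(img@pixels)
  if (cropWidthPx > d[2L] || cropHeightPx > d[1L])
    stop("crop window exceeds image dimensions")
  if (cropWidthPx < 1 || cropHeightPx < 1) stop("crop window must be positive")
  x0 <- (d[2L] - cropWidthPx) %/% 2L + offset[1L]
  y0 <- (d[1L] - cropHeightPx) %/% 2L + offset[2L]
  if (x0 < 0L || y0 < 0L || x0 + cropWidthPx > d[2L] ||
      y0 + cropHeightPx > d[1L])
    stop("crop window (with offset) falls outside the image")
  rows <- (y0 + 1L):(y0 + cropHeightPx)
  cols <- (x0 + 1L):(x0 + cropWidthPx)
  px <- if (length(d) == 2L) img@pixels[rows, cols, drop = FALSE]
        else img@pixels[rows, cols, , drop = FALSE]
  fov <- img@fovMM * c(cropWidthPx / d[2L], cropHeightPx / d[1L])
  calibratedImage(px, fovMM = fov, modality = img@modality)
}

#' Register two skeletons by integer translation
#'
#' Finds the integer shift `(dx, dy)` that, applied to `moving`, best aligns
#' it with `reference` under normalized cross-correlation, searched
#' exhaustively within `±searchPx` (computed via zero-padded FFT
#' cross-correlation, which equals the direct overlap count). Ties are
#' broken toward the smallest |dx| + |dy|, then the smallest dy, then the
#' smallest dx. Both modalities are resampled to a common mm-per-pixel grid
#' before registration, so translation-only alignment suffices.
#'
#' @param reference,moving [BinaryMask-class] objects of equal dimensions.
#' @param searchPx non-negative search radius in pixels.
#' @return A list with integer `dx`, `dy` and the matching `score`
#'   (normalized cross-correlation at the optimum).
#' @examples
#' m <- matrix(FALSE, 32, 32); m[10:20, 16] <- TRUE
#' registerTranslation(binaryMask(m), binaryMask(m), searchPx = 5)
#' @export
registerTranslation <- function(reference, moving, searchPx = 10L) {
  stopifnot(is(reference, "BinaryMask"), is(moving, "BinaryMask"),
            searchPx >= 0)
  a <- reference@mask; b <- moving@mask
  if (!identical(dim(a), dim(b))) stop("masks must share dimensions")
  if (!any(a) || !any(b)) stop("cannot register empty mask")
  s <- as.integer(searchPx)
  n <- dim(a) + 2L * s
  N <- c(.nextPow2(n[1L]), .nextPow2(n[2L]))
  pa <- matrix(0, N[1L], N[2L]); pb <- pa
  pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  # C[dy, dx] = sum_{y,x} a(y,x) * b(y - dy, x - dx)
  C <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)),
                     inverse = TRUE)) / prod(N)
  shifts <- expand.grid(dy = -s:s, dx = -s:s)
  iy <- (shifts$dy %% N[1L]) + 1L
  ix <- (shifts$dx %% N[2L]) + 1L
  sc <- round(C[cbind(iy, ix)])  # overlap counts are integers
  best <- max(sc)
  cand <- which(sc == best)
  key <- abs(shifts$dx[cand]) + abs(shifts$dy[cand])
  cand <- cand[order(key, shifts$dy[cand], shifts$dx[cand])][1L]
  list(dx = as.integer(shifts$dx[cand]), dy = as.integer(shifts$dy[cand]),
       score = best / sqrt(sum(a) * sum(b)))
}

#' Tri-color overlay of two skeletons
#'
#' Paints skeleton `a` pixels that lie within `tolerancePx` (Chebyshev
#' distance) of a skeleton `b` pixel yellow (agreement between both
#' sources), remaining `a` pixels red, `b` pixels not matched by `a` green,
#' and background black.
#'
#' @param a,b [BinaryMask-class] objects of equal dimensions (conventionally
#'   a = angiogram-derived, b = photograph-derived skeleton).
#' @param tolerancePx non-negative match tolerance in pixels.
#' @return A [CalibratedImage-class] with RGB pixels (modality "overlay";
#'   FOV 1 mm/px nominal unless both inputs came from calibrated images).
#' @export
overlaySkeletons <- function(a, b, tolerancePx = 0L) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"), tolerancePx >= 0)
  ma <- a@mask; mb <- b@mask
  if (!identical(dim(ma), dim(mb))) stop("masks must share dimensions")
  t <- as.integer(tolerancePx)
  dilate8 <- function(m, t) {
    if (t == 0L) return(m)
    EBImage::dilate(m, EBImage::makeBrush(2L * t + 1L, "box")) > 0
  }
  da <- dilate8(ma, t); db <- dilate8(mb, t)
  yellow <- ma & db
  red <- ma & !db
  green <- mb & !da
  out <- array(0, c(dim(ma), 3L))
  out[, , 1L] <- (red | yellow) * 1
  out[, , 2L] <- (green | yellow) * 1
  calibratedImage(out, fovMM = rev(dim(ma)), modality = "overlay")
}
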