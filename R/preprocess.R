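# Quantize [0,1] intensities to 0..255 levels and back.
.toLevels <- function(px) {
  lv <- round(.clamp01(px) * 255)
  storage.mode(lv) <- "integer"
  lv
}

#' Convert an RGB image to grayscale
#'
#' Default method `"green"` extracts the green channel — the photographic
#' modality images vessels through a built-in green filter, where hemoglobin
#' contrast is strongest. Method `"luminance"` uses Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B). Grayscale input is returned unchanged.
#'
#' @param img a [CalibratedImage-class] (RGB or already grayscale).
#' @param method `"green"` or `"luminance"`.
#' @return A grayscale [CalibratedImage-class].
#' @export
toGrayscale <- function(img, method = c("green", "luminance")) {
  stopifnot(is(img, "CalibratedImage"))
  method <- match.arg(method)
  d <- dim(img@pixels)
  if (length(d) == 2L) {
    message("toGrayscale: input already grayscale; returned unchanged")
    return(img)
  }
  px <- if (method == "green") img@pixels[, , 2L]
        else {
          # round in 8-bit level space so stated weights are exact there
          lv <- round(0.299 * round(img@pixels[, , 1L] * 255) +
                      0.587 * round(img@pixels[, , 2L] * 255) +
                      0.114 * round(img@pixels[, , 3L] * 255))
          lv / 255
        }
  calibratedImage(px, fovMM = img@fovMM, modality = img@modality)
}

#' Global histogram equalization
#'
#' Classic 256-level equalization: each level v maps to
#' `round(255 * cdf(v))` with the cumulative distribution taken over the
#' image's 256-bin histogram. A constant image has no contrast to spread and
#' maps to all-zero (the minimum output level) rather than raising an error.
#'
#' @param img a grayscale [CalibratedImage-class].
#' @return The equalized image (dims and FOV preserved).
#' @export
equalizeGlobal <- function(img) {
  stopifnot(is(img, "CalibratedImage"))
  if (length(dim(img@pixels)) != 2L) stop("equalizeGlobal expects grayscale")
  lv <- .toLevels(img@pixels)
  h <- tabulate(lv + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)  # constant image: anchor to 0
    return(calibratedImage(matrix(0, nrow(lv), ncol(lv)),
                           fovMM = img@fovMM, modality = img@modality))
  cdf <- cumsum(h) / length(lv)
  map <- round(255 * cdf)
  out <- matrix(map[lv + 1L] / 255, nrow(lv), ncol(lv))
  calibratedImage(out, fovMM = img@fovMM, modality = img@modality)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Equalizes over a `tiles` x `tiles` grid of local histograms with bilinear
#' blending of the per-tile transfer functions between tile centers. Each
#' tile histogram is clipped at `clipLimit` (a fraction of the tile's pixel
#' mass) with the excess redistributed uniformly, limiting noise
#' amplification in flat regions. With `tiles = 1` and `clipLimit = Inf`
#' this degenerates exactly to [equalizeGlobal()].
#'
#' @param img a grayscale [CalibratedImage-class].
#' @param tiles tiles per axis (>= 1); each tile must be at least 2 px.
#' @param clipLimit histogram clip as a fraction of tile mass in (0, 1], or
#'   `Inf` for no clipping.
#' @return The equalized image (dims and FOV preserved).
#' @export
equalizeAdaptive <- function(img, tiles = 8L, clipLimit = 0.01) {
  stopifnot(is(img, "CalibratedImage"))
  if (length(dim(img@pixels)) != 2L) stop("equalizeAdaptive expects grayscale")
  tiles <- as.integer(tiles)
  if (tiles < 1L) stop("tiles must be >= 1")
  if (tiles == 1L && !is.finite(clipLimit)) return(equalizeGlobal(img))
  lv <- .toLevels(img@pixels)
  nr <- nrow(lv); nc <- ncol(lv)
  if (min(nr, nc) / tiles < 2) stop("tiles smaller than 2 px")
  # tile boundaries (half-open) and centers
  rb <- round(seq(0L, nr, length.out = tiles + 1L))
  cb <- round(seq(0L, nc, length.out = tiles + 1L))
  maps <- array(0, c(tiles, tiles, 256L))  # transfer: 255 * clipped cdf
  for (ti in seq_len(tiles)) for (tj in seq_len(tiles)) {
    sub <- lv[(rb[ti] + 1L):rb[ti + 1L], (cb[tj] + 1L):cb[tj + 1L]]
    h <- tabulate(sub + 1L, nbins = 256L)
    if (is.finite(clipLimit)) {
      cap <- clipLimit * length(sub)
      excess <- sum(pmax(h - cap, 0))
      h <- pmin(h, cap) + excess / 256
    }
    maps[ti, tj, ] <- 255 * cumsum(h) / sum(h)
  }
  rc <- (rb[-1L] + rb[-(tiles + 1L)]) / 2  # tile centers (0-based + .5 ok)
  cc <- (cb[-1L] + cb[-(tiles + 1L)]) / 2
  # fractional tile coordinates of every pixel center
  tileCoord <- function(pos, centers) {
    i <- findInterval(pos, centers)          # 0..tiles
    i0 <- pmax(i, 1L); i1 <- pmin(i + 1L, length(centers))
    w <- ifelse(i0 == i1, 0,
                (pos - centers[i0]) / (centers[i1] - centers[i0]))
    list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
  }
  ry <- tileCoord(seq_len(nr) - 0.5, rc)
  cx <- tileCoord(seq_len(nc) - 0.5, cc)
  I0 <- matrix(ry$i0, nr, nc); I1 <- matrix(ry$i1, nr, nc)
  J0 <- matrix(cx$i0, nr, nc, byrow = TRUE)
  J1 <- matrix(cx$i1, nr, nc, byrow = TRUE)
  WY <- matrix(ry$w, nr, nc); WX <- matrix(cx$w, nr, nc, byrow = TRUE)
  look <- function(I, J) maps[cbind(as.vector(I), as.vector(J),
                                    as.vector(lv) + 1L)]
  v <- (1 - WY) * (1 - WX) * look(I0, J0) + (1 - WY) * WX * look(I0, J1) +
       WY * (1 - WX) * look(I1, J0) + WY * WX * look(I1, J1)
  out <- matrix(round(v) / 255, nr, nc)
  calibratedImage(out, fovMM = img@fovMM, modality = img@modality)
}

#' Remove smooth background, turning dark vessels into bright foreground
#'
#' Black-top-hat style background removal for photographs, where vessels are
#' dark tubes on a bright, slowly varying background: the image is inverted,
#' its morphological opening with a disk of radius `openingRadiusPx` (which
#' erases structures narrower than the disk) is subtracted, and the result —
#' now bright vessels on a near-zero background — is clipped to [0, 1]. The
#' radius must exceed the widest vessel's displayed half-width, otherwise
#' vessels survive the opening and are subtracted away; structures wider
#' than the disk (glare, lids) survive the opening and cancel out.
#'
#' @param img a grayscale [CalibratedImage-class] with dark vessels.
#' @param openingRadiusPx disk radius in px (>= 1 and < min(dim) / 2).
#' @return A [CalibratedImage-class] with bright vessels on a dark field.
#' @export
removeBackground <- function(img, openingRadiusPx = 15L) {
  stopifnot(is(img, "CalibratedImage"))
  if (length(dim(img@pixels)) != 2L) stop("removeBackground expects grayscale")
  r <- as.integer(openingRadiusPx)
  if (r < 1L) stop("opening radius must be >= 1")
  if (r > min(dim(img@pixels)) / 2) stop("opening radius too large for image")
  inv <- 1 - img@pixels
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  opened <- as.matrix(EBImage::opening(inv, brush))
  out <- .clamp01(inv - opened)
  calibratedImage(out, fovMM = img@fovMM, modality = img@modality)
}
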