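#' @import methods
NULL

#' CalibratedImage: a raster image with a physical field of view
#'
#' The unit of exchange between all processing stages: a 2-D intensity grid
#' (grayscale matrix or height x width x 3 RGB array, values in [0, 1])
#' together with its physical field of view (FOV) in mm and a modality tag.
#' The physical scale in mm per pixel is `fovMM / dim` per axis and is
#' carried consistently through resizing (FOV unchanged) and cropping (FOV
#' shrinks with the window).
#'
#' @slot pixels numeric matrix (grayscale) or 3-D array with third dim 3
#'   (RGB), values in [0, 1], indexed [row, col] from the top-left.
#' @slot fovMM numeric(2), physical width and height of the image in mm.
#' @slot modality character tag, e.g. "octa_like" or "fslb_like".
#'
#' @seealso [calibratedImage()], [mmPerPixel()], [resizeImage()],
#'   [centerCrop()]
#' @export
setClass("CalibratedImage",
  representation(pixels = "array", fovMM = "numeric", modality = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!(length(d) == 2L || (length(d) == 3L && d[3L] == 3L)))
      return("pixels must be a matrix or an array with 3 channels")
    if (any(d[1:2] < 1L)) return("pixels must have positive dimensions")
    if (length(object@fovMM) != 2L || any(!is.finite(object@fovMM)) ||
        any(object@fovMM <= 0))
      return("fovMM must be two positive finite numbers (width, height) in mm")
    if (length(object@modality) != 1L) return("modality must be a single tag")
    if (any(!is.finite(object@pixels))) return("pixels must be finite")
    TRUE
  })

#' Construct a CalibratedImage
#'
#' @param pixels numeric matrix or height x width x 3 array in [0, 1].
#' @param fovMM numeric(2): physical (width, height) of the image in mm.
#' @param modality character tag recording the image source.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- calibratedImage(matrix(runif(64), 8, 8), fovMM = c(2, 2))
#' mmPerPixel(img)
#' @export
calibratedImage <- function(pixels, fovMM, modality = "unknown") {
  if (is.matrix(pixels)) storage.mode(pixels) <- "double"
  new("CalibratedImage", pixels = pixels, fovMM = as.numeric(fovMM),
      modality = modality)
}

#' BinaryMask: a boolean vessel map
#'
#' @slot mask logical matrix; TRUE marks vessel (foreground) pixels.
#' @slot provenance character, identifier of the source image.
#' @slot threshold numeric, the binarization threshold used (on the 0..255
#'   level scale), or NA when not applicable.
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", provenance = "character",
                 threshold = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    if (any(is.na(object@mask))) return("mask must not contain NA")
    TRUE
  })

#' @rdname BinaryMask-class
#' @param mask logical matrix.
#' @param provenance character identifier for the source image.
#' @param threshold numeric threshold used to produce the mask, if any.
#' @return A [BinaryMask-class] object.
#' @export
binaryMask <- function(mask, provenance = "", threshold = NA_real_) {
  storage.mode(mask) <- "logical"
  new("BinaryMask", mask = mask, provenance = provenance,
      threshold = as.numeric(threshold))
}

#' SkeletonMask: a one-pixel-thin vessel centerline map
#'
#' A [BinaryMask-class] that additionally guarantees thinness: no 2 x 2
#' block of the mask is entirely foreground. Produced by [skeletonize()]
#' and [groundTruthSkeleton()].
#' @export
setClass("SkeletonMask", contains = "BinaryMask",
  validity = function(object) {
    m <- object@mask
    if (nrow(m) >= 2L && ncol(m) >= 2L) {
      a <- m[-nrow(m), , drop = FALSE] & m[-1L, , drop = FALSE]
      if (any(a[, -ncol(a), drop = FALSE] & a[, -1L, drop = FALSE]))
        return("skeleton is not thin: found a 2x2 all-foreground block")
    }
    TRUE
  })

#' @rdname SkeletonMask-class
#' @param mask logical matrix satisfying the thinness invariant.
#' @param provenance character identifier for the source image.
#' @return A [SkeletonMask-class] object.
#' @export
skeletonMask <- function(mask, provenance = "") {
  storage.mode(mask) <- "logical"
  new("SkeletonMask", mask = mask, provenance = provenance,
      threshold = NA_real_)
}

#' GroundTruthNetwork: synthetic vessel centerlines with calibers
#'
#' The shared ground truth consumed by both modality renderers: a set of
#' centerline polylines in physical mm coordinates, one caliber (width) per
#' polyline, inside a bounding FOV.
#'
#' @slot segments list of n x 2 matrices, columns (x_mm, y_mm).
#' @slot widthsMM numeric vessel caliber in mm, one per segment.
#' @slot fovMM numeric(2) bounding field of view (width, height) in mm.
#' @seealso [generateNetwork()], [renderModality()], [groundTruthSkeleton()]
#' @export
setClass("GroundTruthNetwork",
  representation(segments = "list", widthsMM = "numeric", fovMM = "numeric"),
  validity = function(object) {
    if (length(object@segments) != length(object@widthsMM))
      return("one width per segment required")
    if (length(object@fovMM) != 2L || any(object@fovMM <= 0))
      return("fovMM must be two positive numbers")
    if (length(object@widthsMM) && any(object@widthsMM <= 0))
      return("vessel widths must be positive")
    eps <- 1e-9
    for (s in object@segments) {
      if (!is.matrix(s) || ncol(s) != 2L || nrow(s) < 2L)
        return("each segment must be an n x 2 matrix of vertices, n >= 2")
      if (any(s[, 1L] < -eps) || any(s[, 1L] > object@fovMM[1L] + eps) ||
          any(s[, 2L] < -eps) || any(s[, 2L] > object@fovMM[2L] + eps))
        return("all polyline vertices must lie inside the FOV")
    }
    TRUE
  })

#' BoxCountResult: box-counting tally and fitted fractal dimension
#'
#' @slot sizesPx numeric, strictly decreasing box side lengths in pixels.
#' @slot counts numeric, occupied-box counts N(s), one per size.
#' @slot dbox numeric(1), OLS slope of log N(s) on log(1/s).
#' @slot rSquared numeric(1), coefficient of determination of the fit.
#' @slot intercept numeric(1), intercept of the log-log fit.
#' @seealso [boxCount()]
#' @export
setClass("BoxCountResult",
  representation(sizesPx = "numeric", counts = "numeric", dbox = "numeric",
                 rSquared = "numeric", intercept = "numeric"),
  validity = function(object) {
    if (length(object@sizesPx) != length(object@counts))
      return("sizes and counts must have equal length")
    if (any(diff(object@sizesPx) >= 0))
      return("sizes must be strictly decreasing")
    if (any(object@counts <= 0)) return("counts must be positive")
    if (any(diff(object@counts) < 0))
      return("counts must be non-decreasing as box size decreases")
    TRUE
  })

#' SyntheticConfig: parameters of the vascular network generator
#'
#' @slot seed integer RNG seed; the network is a pure function of the config.
#' @slot nRoots integer, number of seed vessels (0 gives an empty network).
#' @slot branchProbability numeric in [0, 1], per-step branching chance.
#' @slot meanSegmentLenMM numeric, mean unbranched vessel run length in mm.
#' @slot widthRangeMM numeric(2), (min, max) root caliber in mm; bounded by
#'   0.2 mm, the upper end of conjunctival vessel calibers.
#' @slot fovMM numeric(2), bounding field of view in mm.
#' @seealso [syntheticConfig()], [generateNetwork()]
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", nRoots = "integer",
                 branchProbability = "numeric", meanSegmentLenMM = "numeric",
                 widthRangeMM = "numeric", fovMM = "numeric"),
  validity = function(object) {
    if (object@nRoots < 0L) return("nRoots must be >= 0")
    if (object@branchProbability < 0 || object@branchProbability > 1)
      return("branchProbability must be in [0, 1]")
    if (object@meanSegmentLenMM <= 0)
      return("meanSegmentLenMM must be positive")
    w <- object@widthRangeMM
    if (length(w) != 2L || w[1L] <= 0 || w[2L] > 0.2 || w[1L] > w[2L])
      return("widthRangeMM must satisfy 0 < min <= max <= 0.2 mm")
    if (length(object@fovMM) != 2L || any(object@fovMM <= 0))
      return("fovMM must be two positive numbers")
    TRUE
  })

#' ModalityParams: rendering parameters of one imaging modality
#'
#' Describes how a ground-truth network is turned into an image: native
#' pixel grid, physical FOV, noise model, vignetting, background level and
#' vessel polarity. The two built-in profiles mirror the instruments being
#' emulated: `"octa_like"` is a coarse 304 x 304 grid over 8.775 x 8.775
#' mm^2 with multiplicative speckle and bright vessels; `"fslb_like"` is a
#' fine 5184 x 3456 grid over 15.74 x 10.50 mm^2 with additive Gaussian
#' noise, radial vignetting and dark vessels on a bright background (a
#' green-filter photograph).
#'
#' @slot modality character profile tag.
#' @slot nativeGrid integer(2), native (width, height) in pixels.
#' @slot fovMM numeric(2), physical (width, height) in mm.
#' @slot noiseModel `"speckle"` (multiplicative exponential) or
#'   `"gaussian"` (additive).
#' @slot noiseLevel numeric >= 0, noise strength (blend weight for speckle,
#'   standard deviation for gaussian).
#' @slot vignettingStrength numeric in [0, 1], radial intensity falloff.
#' @slot backgroundLevel numeric in [0, 1], tissue background intensity.
#' @slot vesselPolarity `"bright"` or `"dark"` relative to background.
#' @slot minDetectableMM numeric >= 0, smallest vessel caliber the contrast
#'   mechanism can register; vessels below it are not rendered (flow
#'   decorrelation imaging fails outright for vessels much thinner than the
#'   transverse sampling interval, whereas absorption photography renders
#'   arbitrarily thin vessels, only diluted).
#' @slot flowFloor numeric in [0, 1]; after noise, intensities below this
#'   level are displayed as 0 (flow-contrast instruments suppress
#'   decorrelation values under their noise threshold, leaving vessels on a
#'   near-black background with only sparse noise survivors; 0 disables).
#' @seealso [modalityParams()], [renderModality()]
#' @export
setClass("ModalityParams",
  representation(modality = "character", nativeGrid = "integer",
                 fovMM = "numeric", noiseModel = "character",
                 noiseLevel = "numeric", vignettingStrength = "numeric",
                 backgroundLevel = "numeric", vesselPolarity = "character",
                 minDetectableMM = "numeric", flowFloor = "numeric"),
  validity = function(object) {
    if (length(object@nativeGrid) != 2L || any(object@nativeGrid < 1L))
      return("nativeGrid must be two positive integers")
    if (length(object@fovMM) != 2L || any(object@fovMM <= 0))
      return("fovMM must be two positive numbers")
    if (!object@noiseModel %in% c("speckle", "gaussian"))
      return("noiseModel must be 'speckle' or 'gaussian'")
    if (object@noiseLevel < 0) return("noiseLevel must be >= 0")
    if (object@vignettingStrength < 0 || object@vignettingStrength > 1)
      return("vignettingStrength must be in [0, 1]")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
      return("backgroundLevel must be in [0, 1]")
    if (!object@vesselPolarity %in% c("bright", "dark"))
      return("vesselPolarity must be 'bright' or 'dark'")
    if (length(object@minDetectableMM) != 1L || object@minDetectableMM < 0)
      return("minDetectableMM must be a single number >= 0")
    if (length(object@flowFloor) != 1L || object@flowFloor < 0 ||
        object@flowFloor > 1)
      return("flowFloor must be a single number in [0, 1]")
    TRUE
  })

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage [%s]: %d x %d px%s, FOV %.3f x %.3f mm, %s\n",
              object@modality, d[2L], d[1L],
              if (length(d) == 3L) " (RGB)" else "",
              object@fovMM[1L], object@fovMM[2L],
              sprintf("%.2f um/px", 1000 * object@fovMM[1L] / d[2L])))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("%s: %d x %d px, %d foreground (%.2f%%)%s\n",
              class(object), ncol(object@mask), nrow(object@mask),
              sum(object@mask), 100 * mean(object@mask),
              if (is.na(object@threshold)) ""
              else sprintf(", threshold %g", object@threshold)))
})

setMethod("show", "GroundTruthNetwork", function(object) {
  tot <- sum(vapply(object@segments, function(s)
    sum(sqrt(rowSums(diff(s)^2))), numeric(1)))
  cat(sprintf(
    "GroundTruthNetwork: %d segments, %.2f mm total length, FOV %.2f x %.2f mm\n",
    length(object@segments), tot, object@fovMM[1L], object@fovMM[2L]))
})

setMethod("show", "BoxCountResult", function(object) {
  cat(sprintf("BoxCountResult: Dbox = %.4f (R^2 = %.4f), %d box sizes %d..%d px\n",
              object@dbox, object@rSquared, length(object@sizesPx),
              as.integer(max(object@sizesPx)), as.integer(min(object@sizesPx))))
})
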