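#' Accessors for microvasq data classes
#'
#' `pixels()` returns the intensity grid of a [CalibratedImage-class];
#' `fovMM()` its physical field of view in mm; `fovReport()` the FOV rounded
#' to three decimals, the convention used when reporting calibrated extents;
#' `modality()` the modality tag; `mmPerPixel()` the physical sampling pitch
#' per axis; `maskPixels()` the logical grid of a [BinaryMask-class];
#' `maskThreshold()` the binarization level that produced it; `dbox()`,
#' `boxSizes()`, `boxCounts()` and `rSquared()` the components of a
#' [BoxCountResult-class]; `networkSegments()`, `networkWidths()` and
#' `totalLengthMM()` the components of a [GroundTruthNetwork-class].
#'
#' @param x the object.
#' @return The slot value (see details per generic above).
#' @examples
#' img <- calibratedImage(matrix(0.5, 768, 1024), fovMM = c(8.775, 6.581))
#' mmPerPixel(img)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("fovMM", function(x) standardGeneric("fovMM"))
#' @rdname accessors
#' @export
setMethod("fovMM", "CalibratedImage", function(x) x@fovMM)
#' @rdname accessors
#' @export
setMethod("fovMM", "GroundTruthNetwork", function(x) x@fovMM)
#' @rdname accessors
#' @export
setMethod("fovMM", "ModalityParams", function(x) x@fovMM)

#' @rdname accessors
#' @export
setGeneric("fovReport", function(x) standardGeneric("fovReport"))
#' @rdname accessors
#' @export
setMethod("fovReport", "CalibratedImage", function(x) round(x@fovMM, 3))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setMethod("modality", "CalibratedImage", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("modality", "ModalityParams", function(x) x@modality)

#' @rdname accessors
#' @export
setGeneric("mmPerPixel", function(x) standardGeneric("mmPerPixel"))
#' @rdname accessors
#' @export
setMethod("mmPerPixel", "CalibratedImage", function(x) {
  d <- dim(x@pixels)
  c(x@fovMM[1L] / d[2L], x@fovMM[2L] / d[1L])
})

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))
#' @rdname accessors
#' @export
setMethod("maskThreshold", "BinaryMask", function(x) x@threshold)

#' @rdname accessors
#' @export
setGeneric("dbox", function(x) standardGeneric("dbox"))
#' @rdname accessors
#' @export
setMethod("dbox", "BoxCountResult", function(x) x@dbox)

#' @rdname accessors
#' @export
setGeneric("boxSizes", function(x) standardGeneric("boxSizes"))
#' @rdname accessors
#' @export
setMethod("boxSizes", "BoxCountResult", function(x) x@sizesPx)

#' @rdname accessors
#' @export
setGeneric("boxCounts", function(x) standardGeneric("boxCounts"))
#' @rdname accessors
#' @export
setMethod("boxCounts", "BoxCountResult", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "BoxCountResult", function(x) x@rSquared)

#' @rdname accessors
#' @export
setGeneric("networkSegments", function(x) standardGeneric("networkSegments"))
#' @rdname accessors
#' @export
setMethod("networkSegments", "GroundTruthNetwork", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("networkWidths", function(x) standardGeneric("networkWidths"))
#' @rdname accessors
#' @export
setMethod("networkWidths", "GroundTruthNetwork", function(x) x@widthsMM)

#' @rdname accessors
#' @export
setGeneric("totalLengthMM", function(x) standardGeneric("totalLengthMM"))
#' @rdname accessors
#' @export
setMethod("totalLengthMM", "GroundTruthNetwork", function(x) {
  if (!length(x@segments)) return(0)
  sum(vapply(x@segments, function(s) sum(sqrt(rowSums(diff(s)^2))),
             numeric(1)))
})

#' @rdname accessors
#' @export
setMethod("dim", "CalibratedImage", function(x) dim(x@pixels)[1:2])
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@mask))
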