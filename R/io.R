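#' Read a raster image with its physical calibration
#'
#' Reads PNG, TIFF or uncompressed BMP into a [CalibratedImage-class]. The
#' physical field of view must be supplied either through `fovMM` or through
#' a YAML sidecar file (`<image>.yaml` next to the image, fields `fov_mm:
#' [w, h]` and optionally `modality:`); images carry no physical scale on
#' their own, and every downstream density readout depends on it.
#'
#' @param path path to a PNG/TIFF/BMP file.
#' @param fovMM numeric(2) physical (width, height) in mm; overrides the
#'   sidecar when both are present.
#' @param modality modality tag; overrides the sidecar.
#' @return A [CalibratedImage-class]; 8-bit grayscale files round-trip
#'   pixel-exactly through [writeCalibratedImage()].
#' @examples
#' f <- tempfile(fileext = ".png")
#' img <- calibratedImage(matrix((0:63) / 255, 8, 8), c(1, 1), "octa_like")
#' writeCalibratedImage(img, f)
#' img2 <- readCalibratedImage(f)
#' identical(pixels(img), pixels(img2))
#' @export
readCalibratedImage <- function(path, fovMM = NULL, modality = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = .readBMP(path),
    stop("unsupported format '", ext, "' (supported: PNG, BMP, TIFF)"))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    else if (dim(px)[3L] >= 3L) px <- px[, , 1:3]  # drop alpha
  }
  side <- .readSidecar(path)
  if (is.null(fovMM)) fovMM <- side$fov_mm
  if (is.null(fovMM))
    stop("FOV required: supply fovMM or a '", basename(path),
         ".yaml' sidecar with a fov_mm field")
  if (is.null(modality))
    modality <- if (!is.null(side$modality)) side$modality else "unknown"
  calibratedImage(px, fovMM = as.numeric(fovMM), modality = modality)
}

#' Write a calibrated image plus its metadata sidecar
#'
#' Writes 8-bit PNG (default), TIFF or uncompressed 24-bit BMP according to
#' the file extension, and a YAML sidecar `<path>.yaml` carrying `fov_mm`
#' and `modality` so the image can be re-read without external calibration.
#'
#' @param img a [CalibratedImage-class].
#' @param path output file path (extension selects the format).
#' @param sidecar write the YAML sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
writeCalibratedImage <- function(img, path, sidecar = TRUE) {
  stopifnot(is(img, "CalibratedImage"))
  px <- .clamp01(img@pixels)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    bmp = .writeBMP(px, path),
    stop("unsupported format '", ext, "' (supported: PNG, BMP, TIFF)"))
  if (sidecar)
    yaml::write_yaml(list(fov_mm = as.numeric(img@fovMM),
                          modality = img@modality),
                     paste0(path, ".yaml"))
  invisible(path)
}

.readSidecar <- function(path) {
  for (cand in c(paste0(path, ".yaml"),
                 paste0(tools::file_path_sans_ext(path), ".yaml"))) {
    if (file.exists(cand)) return(yaml::read_yaml(cand))
  }
  NULL
}

# Minimal uncompressed BMP codec (BITMAPINFOHEADER, BI_RGB): 24-bit
# truecolor and 8-bit palette grayscale. No installed package reads BMP.
.readBMP <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readBin(con, "raw", 2L)
  if (!identical(as.integer(sig), c(0x42L, 0x4DL))) stop("not a BMP file")
  readBin(con, "integer", 2L, size = 4L)           # file size, reserved
  offset <- readBin(con, "integer", 1L, size = 4L)
  hdrSize <- readBin(con, "integer", 1L, size = 4L)
  if (hdrSize < 40L) stop("unsupported BMP header")
  w <- readBin(con, "integer", 1L, size = 4L)
  h <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 2L)           # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  comp <- readBin(con, "integer", 1L, size = 4L)
  if (comp != 0L) stop("unsupported BMP: compressed data")
  if (!bpp %in% c(8L, 24L)) stop("unsupported BMP bit depth: ", bpp)
  seek(con, 14L + hdrSize)
  pal <- NULL
  if (bpp == 8L) {
    npal <- (offset - 14L - hdrSize) %/% 4L
    pal <- matrix(as.integer(readBin(con, "raw", 4L * npal)), ncol = 4L,
                  byrow = TRUE)
  }
  seek(con, offset)
  stride <- ((bpp %/% 8L) * w + 3L) %/% 4L * 4L
  raw <- as.integer(readBin(con, "raw", stride * abs(h)))
  rows <- matrix(raw, nrow = stride)  # one column per stored row
  topDown <- h < 0L; h <- abs(h)
  rowOrder <- if (topDown) seq_len(h) else rev(seq_len(h))
  if (bpp == 8L) {
    vals <- rows[seq_len(w), rowOrder, drop = FALSE]  # w x h
    lut <- pal[, 1L]  # palette stored BGRA; grayscale palettes have B==G==R
    out <- matrix(lut[vals + 1L] / 255, nrow = h, byrow = TRUE)
    out
  } else {
    b <- rows[seq(1L, 3L * w, 3L), rowOrder, drop = FALSE]
    g <- rows[seq(2L, 3L * w, 3L), rowOrder, drop = FALSE]
    r <- rows[seq(3L, 3L * w, 3L), rowOrder, drop = FALSE]
    out <- array(0, c(h, w, 3L))
    out[, , 1L] <- t(r) / 255
    out[, , 2L] <- t(g) / 255
    out[, , 3L] <- t(b) / 255
    out
  }
}

.writeBMP <- function(px, path) {
  gray <- is.matrix(px)
  h <- dim(px)[1L]; w <- dim(px)[2L]
  con <- file(path, "wb"); on.exit(close(con))
  if (gray) {
    stride <- (w + 3L) %/% 4L * 4L
    offset <- 14L + 40L + 256L * 4L
    vals <- round(px * 255)
  } else {
    stride <- (3L * w + 3L) %/% 4L * 4L
    offset <- 14L + 40L
    vals <- round(px * 255)
  }
  dataSize <- stride * h
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(offset + dataSize), con, size = 4L)
  writeBin(0L, con, size = 4L)
  writeBin(as.integer(offset), con, size = 4L)
  writeBin(40L, con, size = 4L)
  writeBin(as.integer(w), con, size = 4L)
  writeBin(as.integer(h), con, size = 4L)
  writeBin(1L, con, size = 2L)
  writeBin(if (gray) 8L else 24L, con, size = 2L)
  writeBin(integer(2L), con, size = 4L)            # compression, image size
  writeBin(c(2835L, 2835L), con, size = 4L)        # 72 dpi
  writeBin(integer(2L), con, size = 4L)            # palette counts
  if (gray) {
    pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))
    writeBin(pal, con)
    for (r in rev(seq_len(h))) {
      row <- as.integer(vals[r, ])
      writeBin(as.raw(c(row, integer(stride - w))), con)
    }
  } else {
    for (r in rev(seq_len(h))) {
      bgr <- as.integer(rbind(vals[r, , 3L], vals[r, , 2L], vals[r, , 1L]))
      writeBin(as.raw(c(bgr, integer(stride - 3L * w))), con)
    }
  }
  invisible(path)
}
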