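#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. The geometry
#' defaults mirror the calibrated processing chain: images are first
#' resampled to a 1024-px-wide grid, the central 6.58125 x 6.58125 mm^2
#' window is cropped (768 px out of 1024 px when the FOV is 8.775 mm,
#' reported as 6.581 mm), and the crop is resampled to the 768 x 768 working
#' grid on which segmentation (Gaussian sigma 4 px, bandpass 40/3 px, Otsu,
#' skeletonization) and quantification (largest box 104 px, 15 box sizes)
#' operate.
#'
#' @param workingPx working grid side in pixels.
#' @param preResizeWidthPx width of the intermediate resample, px.
#' @param targetFovMM physical side of the analysis window, mm.
#' @param sigmaPx Gaussian blur sigma, px.
#' @param bpLargePx,bpSmallPx bandpass structure-size cutoffs, px.
#' @param largestBoxPx,nBoxSizes box-counting settings.
#' @param adaptiveTiles,clipLimit photograph CLAHE settings.
#' @param openRadiusPx photograph background-removal disk radius, px.
#' @param grayMethod grayscale conversion for RGB photographs.
#' @param seed integer seed recorded with the run.
#' @return A list of class `"PipelineConfig"`.
#' @seealso [runSingle()], [runPairedStudy()], [writePipelineConfig()]
#' @export
pipelineConfig <- function(workingPx = 768L, preResizeWidthPx = 1024L,
                           targetFovMM = 8.775 * 768 / 1024, sigmaPx = 4,
                           bpLargePx = 40, bpSmallPx = 3,
                           largestBoxPx = 104L, nBoxSizes = 15L,
                           adaptiveTiles = 8L, clipLimit = 0.01,
                           openRadiusPx = 15L, grayMethod = "green",
                           seed = 42L) {
  cfg <- list(workingPx = as.integer(workingPx),
              preResizeWidthPx = as.integer(preResizeWidthPx),
              targetFovMM = targetFovMM, sigmaPx = sigmaPx,
              bpLargePx = bpLargePx, bpSmallPx = bpSmallPx,
              largestBoxPx = as.integer(largestBoxPx),
              nBoxSizes = as.integer(nBoxSizes),
              adaptiveTiles = as.integer(adaptiveTiles),
              clipLimit = clipLimit, openRadiusPx = as.integer(openRadiusPx),
              grayMethod = grayMethod, seed = as.integer(seed))
  # delegate validation to the stage constructors
  boxCountConfig(cfg$largestBoxPx, cfg$nBoxSizes)
  if (cfg$bpLargePx <= cfg$bpSmallPx || cfg$bpSmallPx <= 0)
    stop("bandpass cutoffs must satisfy large > small > 0")
  if (cfg$sigmaPx <= 0) stop("sigma must be positive")
  if (cfg$workingPx < 2L || cfg$preResizeWidthPx < 2L)
    stop("grid sizes must be positive")
  structure(cfg, class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' Serialization is a faithful round trip: `readPipelineConfig()` of a
#' written file reproduces the configuration exactly.
#'
#' @param cfg a [pipelineConfig()].
#' @param path YAML file path.
#' @return `path` (write) or the configuration (read).
#' @export
writePipelineConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipelineConfig, v)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage <", name, ">: ", conditionMessage(e), call. = FALSE))
}

.writeStage <- function(outputDir, tag, name, obj) {
  if (is.null(outputDir)) return(invisible(NULL))
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  path <- file.path(outputDir, paste0(tag, "_", name, ".png"))
  if (is(obj, "BinaryMask"))
    png::writePNG(obj@mask * 1, path)
  else writeCalibratedImage(obj, path, sidecar = FALSE)
  invisible(path)
}

#' Run the full quantification pipeline on one calibrated image
#'
#' Executes the modality-appropriate preprocessing, normalizes geometry to
#' the working grid, applies the shared segmentation chain and quantifies
#' the skeleton. Photograph-like images (`modality` containing "fslb") get
#' grayscale conversion, adaptive equalization and morphological background
#' removal (which flips their dark vessels to bright foreground); angiogram
#' like images are taken as grayscale with bright vessels. Geometry then
#' resamples to `preResizeWidthPx`, crops the central `targetFovMM` window
#' and resamples to the working grid; the shared chain is global
#' equalization, Gaussian blur, FFT bandpass, Otsu thresholding and
#' skeletonization. Any stage failure aborts with the stage name in the
#' message. When `outputDir` is given every intermediate is written as PNG.
#'
#' @param img a [CalibratedImage-class].
#' @param cfg a [pipelineConfig()].
#' @param outputDir optional directory for intermediate PNG artifacts.
#' @param subject,eye provenance for the returned record.
#' @return A list with `record` (one-row data.frame), `skeleton`
#'   (a [SkeletonMask-class]), `binary`, `otsuLevel` and `working` (the
#'   working-grid [CalibratedImage-class]).
#' @export
runSingle <- function(img, cfg = pipelineConfig(), outputDir = NULL,
                      subject = NA, eye = NA_character_) {
  stopifnot(is(img, "CalibratedImage"), inherits(cfg, "PipelineConfig"))
  tag <- img@modality
  photo <- grepl("fslb", tag, fixed = TRUE)
  x <- img
  if (length(dim(x@pixels)) == 3L)
    x <- .stage("grayscale", toGrayscale(x, cfg$grayMethod))
  if (photo) {
    x <- .stage("resize", resizeToWidth(x, cfg$preResizeWidthPx))
    .writeStage(outputDir, tag, "c_resized", x)
    x <- .stage("adaptive_equalize",
                equalizeAdaptive(x, cfg$adaptiveTiles, cfg$clipLimit))
    x <- .stage("background_removal",
                removeBackground(x, cfg$openRadiusPx))
    .writeStage(outputDir, tag, "d_enhanced", x)
  } else {
    x <- .stage("resize", resizeToWidth(x, cfg$preResizeWidthPx))
  }
  x <- .stage("crop", {
    mmpp <- mmPerPixel(x)
    cw <- round(cfg$targetFovMM / mmpp[1L])
    ch <- round(cfg$targetFovMM / mmpp[2L])
    centerCrop(x, cw, ch)
  })
  x <- .stage("working_resize",
              resizeImage(x, cfg$workingPx, cfg$workingPx))
  .writeStage(outputDir, tag, "f_working", x)
  x <- .stage("equalize", equalizeGlobal(x))
  .writeStage(outputDir, tag, "g_equalized", x)
  x <- .stage("gaussian_blur", gaussianBlur(x, cfg$sigmaPx))
  .writeStage(outputDir, tag, "i_blurred", x)
  x <- .stage("bandpass", fftBandpass(x, cfg$bpLargePx, cfg$bpSmallPx))
  .writeStage(outputDir, tag, "k_bandpassed", x)
  ot <- .stage("otsu", otsuThreshold(x, provenance = tag))
  .writeStage(outputDir, tag, "m_binary", ot$mask)
  skel <- .stage("skeletonize", skeletonize(ot$mask))
  .writeStage(outputDir, tag, "o_skeleton", skel)
  rec <- .stage("quantify",
                quantifySkeleton(skel,
                                 boxCountConfig(cfg$largestBoxPx,
                                                cfg$nBoxSizes),
                                 subject = subject, eye = eye,
                                 modality = tag))
  list(record = rec, skeleton = skel, binary = ot$mask,
       otsuLevel = ot$level, working = x)
}

#' Simulate and analyze a paired two-modality study
#'
#' Synthetic analog of a paired-device comparison: for each of `nSubjects`
#' subjects, two eyes (OD/OS) each get an independent ground-truth vascular
#' network, rendered through both modality profiles and pushed through the
#' full pipeline. The per-eye density records are then compared between
#' modalities: repeated-measures/paired tests and Bland-Altman limits of
#' agreement for both readouts (differences oriented angiogram minus
#' photograph), cross-device Pearson correlations, and the within-device
#' percent-vs-Dbox correlation. Each eye is treated as an analysis unit; a
#' subject-level averaging option is provided for sensitivity analysis.
#'
#' @param nSubjects number of subjects (>= 2); each contributes two eyes.
#' @param cfg a [pipelineConfig()].
#' @param seed master seed; all networks and noise draws derive from it.
#' @param outDir optional directory for the CSV, JSON report and plots.
#' @param octaParams,fslbParams [ModalityParams-class] render profiles.
#' @param synthDefaults a [SyntheticConfig-class] used as template for the
#'   per-eye networks (its seed is replaced per eye).
#' @param perSubject average the two eyes of each subject before testing.
#' @return A list with `records` (data.frame, one row per eye x modality)
#'   and `stats` (paired tests, correlations, Bland-Altman, mean +/- SD
#'   summaries).
#' @export
runPairedStudy <- function(nSubjects = 10L, cfg = pipelineConfig(),
                           seed = cfg$seed, outDir = NULL,
                           octaParams = modalityParams("octa_like"),
                           fslbParams = modalityParams("fslb_like"),
                           synthDefaults = syntheticConfig(),
                           perSubject = FALSE) {
  if (nSubjects < 2L) stop("need at least 2 subjects")
  records <- list()
  skels <- list()
  for (s in seq_len(nSubjects)) {
    for (ei in 1:2) {
      eye <- c("OD", "OS")[ei]
      eyeSeed <- (as.integer(seed) + 7919L * (2L * (s - 1L) + ei)) %%
        2147483587L
      sc <- synthDefaults
      sc@seed <- as.integer(eyeSeed)
      net <- generateNetwork(sc)
      for (pi in 1:2) {
        params <- list(octaParams, fslbParams)[[pi]]
        img <- renderModality(net, params, seed = eyeSeed + pi)
        res <- runSingle(img, cfg, subject = s, eye = eye)
        records[[length(records) + 1L]] <- res$record
      }
    }
  }
  records <- do.call(rbind, records)
  octa <- records[records$modality == octaParams@modality, ]
  fslb <- records[records$modality == fslbParams@modality, ]
  ord <- order(octa$subject, octa$eye)
  octa <- octa[ord, ]; fslb <- fslb[order(fslb$subject, fslb$eye), ]
  if (perSubject) {
    agg <- function(d) stats::aggregate(
      d[c("density_percent", "dbox")], by = list(subject = d$subject), mean)
    octa <- agg(octa); fslb <- agg(fslb)
    units <- octa$subject
  } else {
    units <- paste(octa$subject, octa$eye)
  }
  st <- list(
    percent = pairedCompare(octa$density_percent, fslb$density_percent,
                            unitIds = units),
    dbox = pairedCompare(octa$dbox, fslb$dbox, unitIds = units),
    pearsonAcrossDevices = list(
      percent = pearsonCor(octa$density_percent, fslb$density_percent),
      dbox = pearsonCor(octa$dbox, fslb$dbox)),
    pearsonWithinDevice = list(
      octa = pearsonCor(octa$density_percent, octa$dbox),
      fslb = pearsonCor(fslb$density_percent, fslb$dbox)),
    blandAltman = list(
      percent = blandAltman(octa$density_percent, fslb$density_percent),
      dbox = blandAltman(octa$dbox, fslb$dbox)),
    summary = list(
      octa = list(percent = meanSD(octa$density_percent),
                  dbox = meanSD(octa$dbox)),
      fslb = list(percent = meanSD(fslb$density_percent),
                  dbox = meanSD(fslb$dbox))))
  report <- list(records = records, stats = st,
                 config = unclass(cfg), seed = as.integer(seed),
                 nSubjects = as.integer(nSubjects))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(records, file.path(outDir, "density_records.csv"),
                     row.names = FALSE)
    clean <- st
    clean$blandAltman <- lapply(st$blandAltman, function(x)
      unclass(x)[c("meanDiff", "sdDiff", "loaLow", "loaHigh", "n")])
    jsonlite::write_json(list(stats = clean, seed = as.integer(seed),
                              nSubjects = as.integer(nSubjects)),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (metric in c("percent", "dbox")) {
      grDevices::png(file.path(outDir, paste0("bland_altman_", metric,
                                              ".png")),
                     width = 700, height = 500)
      plotBlandAltman(st$blandAltman[[metric]],
                      main = paste("Bland-Altman:", metric))
      grDevices::dev.off()
    }
  }
  report
}
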