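#' Configure the synthetic vascular network generator
#'
#' The generator grows a branching random walk: `nRoots` walkers start at
#' random positions and headings inside the FOV, advance in short steps with
#' wrapped-normal heading jitter, spawn a child walker with probability
#' `branchProbability` per step (child caliber tapered by a fixed factor),
#' and terminate on leaving the FOV or, at random, with mean unbranched run
#' length `meanSegmentLenMM`. Calibers are drawn uniformly from
#' `widthRangeMM`, capped at 0.2 mm as conjunctival vessels measure tens of
#' micrometers. The network is a pure function of the configuration,
#' including its seed.
#'
#' @param seed integer RNG seed.
#' @param nRoots number of seed vessels; 0 yields an empty network.
#' @param branchProbability per-step branching probability in [0, 1].
#' @param meanSegmentLenMM mean unbranched vessel run length, mm.
#' @param widthRangeMM numeric(2) (min, max) root caliber, mm.
#' @param fovMM numeric(2) bounding field of view (width, height), mm. The
#'   default spans the photograph-like FOV so both modality renderers can
#'   image central sub-regions of one shared network.
#' @return A [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(seed = 7, nRoots = 4)
#' net <- generateNetwork(cfg)
#' totalLengthMM(net)
#' @export
syntheticConfig <- function(seed = 1L, nRoots = 50L, branchProbability = 0.13,
                            meanSegmentLenMM = 2.5,
                            widthRangeMM = c(0.008, 0.035),
                            fovMM = c(15.74, 10.50)) {
  new("SyntheticConfig", seed = as.integer(seed), nRoots = as.integer(nRoots),
      branchProbability = branchProbability,
      meanSegmentLenMM = meanSegmentLenMM,
      widthRangeMM = as.numeric(widthRangeMM), fovMM = as.numeric(fovMM))
}

#' Rendering parameters for one imaging modality
#'
#' Two built-in profiles emulate the instruments under comparison. The
#' angiogram-like profile (`"octa_like"`) renders on the native 304 x 304
#' A-scan/B-scan grid over the calibrated 8.775 x 8.775 mm^2 FOV with
#' multiplicative speckle and bright vessels; its ~29 um pixel pitch exceeds
#' typical conjunctival capillary calibers, which is the mechanism that
#' depresses measured density downstream. The photograph-like profile
#' (`"fslb_like"`) renders on the native 5184 x 3456 sensor grid over the
#' calibrated 15.74 x 10.50 mm^2 FOV (~3 um pitch) with additive Gaussian
#' noise, radial vignetting and dark vessels on a bright background, as in a
#' green-filter slit-lamp photograph.
#'
#' @param modality `"octa_like"` or `"fslb_like"`.
#' @param nativeGrid integer(2) (width, height) pixels; defaults per profile.
#' @param fovMM numeric(2) physical FOV in mm; defaults per profile.
#' @param noiseModel `"speckle"` or `"gaussian"`; defaults per profile.
#' @param noiseLevel noise strength: blend weight toward unit-mean
#'   exponential speckle, or Gaussian standard deviation (intensity units).
#' @param vignettingStrength radial falloff in [0, 1] (0 disables).
#' @param backgroundLevel background intensity in [0, 1].
#' @param vesselPolarity `"bright"` or `"dark"` vessels.
#' @param minDetectableMM smallest caliber the contrast mechanism registers;
#'   thinner vessels are not rendered at all. Defaults to 0 (disabled) for
#'   both profiles: for `"octa_like"` the loss of sub-sampling-interval
#'   vessels already emerges from the coarse grid itself — a thin vessel
#'   running between A-scan positions contributes only a fraction of its
#'   amplitude to the nearest pixels, which `flowFloor` then suppresses — so
#'   no explicit caliber cutoff is imposed on top.
#' @param flowFloor display noise floor in [0, 1]: after the noise draw,
#'   intensities below it are set to 0, the way flow-contrast instruments
#'   suppress decorrelation values under their noise threshold before
#'   display. Defaults to 0.15 for `"octa_like"` — just above the bulk of
#'   the static-tissue speckle distribution, so the background renders
#'   near-black with sparse noise survivors — and 0 (disabled) for
#'   `"fslb_like"`.
#' @return A [ModalityParams-class] object.
#' @examples
#' modalityParams("octa_like")
#' modalityParams("fslb_like", nativeGrid = c(1296, 864))
#' @export
modalityParams <- function(modality = c("octa_like", "fslb_like"),
                           nativeGrid = NULL, fovMM = NULL, noiseModel = NULL,
                           noiseLevel = NULL, vignettingStrength = NULL,
                           backgroundLevel = NULL, vesselPolarity = NULL,
                           minDetectableMM = NULL, flowFloor = NULL) {
  modality <- match.arg(modality)
  def <- if (modality == "octa_like") {
    list(nativeGrid = c(304L, 304L), fovMM = c(8.775, 8.775),
         noiseModel = "speckle", noiseLevel = 0.3, vignettingStrength = 0,
         backgroundLevel = 0.08, vesselPolarity = "bright",
         minDetectableMM = 0, flowFloor = 0.15)
  } else {
    list(nativeGrid = c(5184L, 3456L), fovMM = c(15.74, 10.50),
         noiseModel = "gaussian", noiseLevel = 0.03,
         vignettingStrength = 0.35, backgroundLevel = 0.78,
         vesselPolarity = "dark", minDetectableMM = 0, flowFloor = 0)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  new("ModalityParams", modality = modality,
      nativeGrid = as.integer(pick(nativeGrid, def$nativeGrid)),
      fovMM = as.numeric(pick(fovMM, def$fovMM)),
      noiseModel = pick(noiseModel, def$noiseModel),
      noiseLevel = pick(noiseLevel, def$noiseLevel),
      vignettingStrength = pick(vignettingStrength, def$vignettingStrength),
      backgroundLevel = pick(backgroundLevel, def$backgroundLevel),
      vesselPolarity = pick(vesselPolarity, def$vesselPolarity),
      minDetectableMM = pick(minDetectableMM, def$minDetectableMM),
      flowFloor = pick(flowFloor, def$flowFloor))
}

# Clip segment p -> q to the rectangle [0,w] x [0,h] (Liang-Barsky).
# Returns NULL when fully outside.
.clipSegment <- function(p, q, w, h) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lim <- c(w, h)[k]
    for (side in 1:2) {
      pp <- if (side == 1) -d[k] else d[k]
      qq <- if (side == 1) p[k] else lim - p[k]
      if (pp == 0) { if (qq < 0) return(NULL) } else {
        r <- qq / pp
        if (pp < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
        else { if (r < t0) return(NULL); if (r < t1) t1 <- r }
      }
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}

#' Generate a synthetic ground-truth vascular network
#'
#' Grows a seedable branching random walk (see [syntheticConfig()]) and
#' returns the resulting centerline polylines with per-vessel calibers, all
#' clipped to the configured FOV. Identical configurations (including seed)
#' yield bitwise-identical networks.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [GroundTruthNetwork-class].
#' @examples
#' net <- generateNetwork(syntheticConfig(seed = 7, nRoots = 3))
#' net
#' @export
generateNetwork <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  fov <- config@fovMM
  if (config@nRoots == 0L)
    return(new("GroundTruthNetwork", segments = list(),
               widthsMM = numeric(0), fovMM = fov))
  .withSeed(config@seed, {
    stepMM <- config@meanSegmentLenMM / 8
    pDie <- stepMM / config@meanSegmentLenMM
    maxWalkers <- 400L
    taper <- 0.8
    minWidth <- config@widthRangeMM[1L] * 0.5
    segments <- list(); widths <- numeric(0)
    # stack of walkers: list(pos, angle, width, generation)
    stack <- vector("list", 0)
    for (i in seq_len(config@nRoots)) {
      stack[[length(stack) + 1L]] <- list(
        pos = c(runif(1, 0.05, 0.95) * fov[1L],
                runif(1, 0.05, 0.95) * fov[2L]),
        angle = runif(1, 0, 2 * pi),
        width = runif(1, config@widthRangeMM[1L], config@widthRangeMM[2L]),
        gen = 0L)
    }
    spawned <- length(stack)
    while (length(stack)) {
      w <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      poly <- matrix(w$pos, 1L, 2L)
      pos <- w$pos; angle <- w$angle
      repeat {
        angle <- angle + rnorm(1, 0, 0.35)
        nxt <- pos + stepMM * c(cos(angle), sin(angle))
        inside <- all(nxt >= 0) && nxt[1L] <= fov[1L] && nxt[2L] <= fov[2L]
        if (!inside) {
          cl <- .clipSegment(pos, nxt, fov[1L], fov[2L])
          if (!is.null(cl)) poly <- rbind(poly, cl[2L, ])
          break
        }
        poly <- rbind(poly, nxt)
        pos <- nxt
        if (spawned < maxWalkers && w$gen < 6L &&
            runif(1) < config@branchProbability) {
          cw <- max(w$width * taper, minWidth)
          stack[[length(stack) + 1L]] <- list(
            pos = pos,
            angle = angle + sample(c(-1, 1), 1L) * runif(1, 0.5, 1.1),
            width = cw, gen = w$gen + 1L)
          spawned <- spawned + 1L
        }
        if (runif(1) < pDie) break
      }
      if (nrow(poly) >= 2L) {
        segments[[length(segments) + 1L]] <- unname(poly)
        widths <- c(widths, w$width)
      }
    }
    new("GroundTruthNetwork", segments = segments, widthsMM = widths,
        fovMM = fov)
  })
}

# Accumulate the tube-response field (max over segments of a Gaussian
# cross-section profile) on a (hPx x wPx) grid covering the central
# fovMM window of the network's FOV. Each pixel integrates the profile
# over its square aperture (approximated by widening the Gaussian by the
# aperture variance p^2/12 and scaling the peak by sigma/sigma_eff), so a
# vessel thinner than the pixel pitch contributes proportionally less
# signal — the sampling physics that penalizes coarse grids. A positive
# minDetectableMM additionally drops vessels below that caliber entirely:
# flow-decorrelation contrast is not merely diluted for vessels much
# thinner than the transverse sampling interval, it fails to register them
# at all (and any monotone contrast stretch downstream would resurrect a
# merely attenuated tube, so dilution cannot express this mechanism).
.tubeField <- function(net, wPx, hPx, fovMM, minDetectableMM = 0) {
  field <- matrix(0, hPx, wPx)
  mmpp <- c(fovMM[1L] / wPx, fovMM[2L] / hPx)
  pitch <- mean(mmpp)
  off <- (net@fovMM - fovMM) / 2   # network coords of the window's top-left
  for (k in seq_along(net@segments)) {
    poly <- net@segments[[k]]
    sigma0 <- net@widthsMM[k] / 2
    sigma <- sqrt(sigma0^2 + pitch^2 / 12)
    amp <- sigma0 / sigma
    if (net@widthsMM[k] < minDetectableMM) next
    reach <- 3 * sigma
    for (e in seq_len(nrow(poly) - 1L)) {
      p <- poly[e, ] - off; q <- poly[e + 1L, ] - off
      # bounding pixel window, expanded by the tube reach
      c0 <- max(1L, floor((min(p[1L], q[1L]) - reach) / mmpp[1L]) + 1L)
      c1 <- min(wPx, ceiling((max(p[1L], q[1L]) + reach) / mmpp[1L]))
      r0 <- max(1L, floor((min(p[2L], q[2L]) - reach) / mmpp[2L]) + 1L)
      r1 <- min(hPx, ceiling((max(p[2L], q[2L]) + reach) / mmpp[2L]))
      if (c0 > c1 || r0 > r1) next
      xs <- ((c0:c1) - 0.5) * mmpp[1L]
      ys <- ((r0:r1) - 0.5) * mmpp[2L]
      px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      py <- matrix(ys, length(ys), length(xs))
      dx <- q[1L] - p[1L]; dy <- q[2L] - p[2L]
      len2 <- dx * dx + dy * dy
      if (len2 == 0) {
        d2 <- (px - p[1L])^2 + (py - p[2L])^2
      } else {
        t <- pmin(pmax(((px - p[1L]) * dx + (py - p[2L]) * dy) / len2, 0), 1)
        d2 <- (px - (p[1L] + t * dx))^2 + (py - (p[2L] + t * dy))^2
      }
      prof <- amp * exp(-d2 / (2 * sigma^2))
      sub <- field[r0:r1, c0:c1, drop = FALSE]
      field[r0:r1, c0:c1] <- pmax(sub, prof)
    }
  }
  field
}

#' Render a ground-truth network as one imaging modality
#'
#' Rasterizes each vessel as a tube with a Gaussian cross-section (sigma =
#' caliber / 2), composes it against the background at the modality's
#' polarity, then applies vignetting and the modality noise model. The
#' rendered window is the central `fovMM(params)` region of the network's
#' FOV. Deterministic given `(net, params, seed)`.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param params a [ModalityParams-class].
#' @param seed integer seed for the noise draw.
#' @return A [CalibratedImage-class] tagged with the modality.
#' @examples
#' net <- generateNetwork(syntheticConfig(seed = 2, nRoots = 3,
#'                                        fovMM = c(4, 4)))
#' img <- renderModality(net, modalityParams("octa_like",
#'   nativeGrid = c(128, 128), fovMM = c(4, 4)), seed = 1)
#' img
#' @export
renderModality <- function(net, params, seed = 0L) {
  stopifnot(is(net, "GroundTruthNetwork"), is(params, "ModalityParams"))
  validObject(params)
  wPx <- params@nativeGrid[1L]; hPx <- params@nativeGrid[2L]
  field <- .tubeField(net, wPx, hPx, params@fovMM, params@minDetectableMM)
  bg <- params@backgroundLevel
  amp <- 0.85
  img <- if (params@vesselPolarity == "bright")
    bg + amp * (1 - bg) * field else bg - amp * bg * field
  if (params@vignettingStrength > 0) {
    cx <- (wPx + 1) / 2; cy <- (hPx + 1) / 2
    r2 <- outer(((seq_len(hPx) - cy) / (hPx / 2))^2,
                ((seq_len(wPx) - cx) / (wPx / 2))^2, "+")
    img <- img * (1 - params@vignettingStrength * r2 / max(r2))
  }
  if (params@noiseLevel > 0) {
    img <- .withSeed(seed, {
      if (params@noiseModel == "speckle")
        img * ((1 - params@noiseLevel) +
                 params@noiseLevel * stats::rexp(length(img)))
      else img + stats::rnorm(length(img), 0, params@noiseLevel)
    })
  }
  if (params@flowFloor > 0) img[img < params@flowFloor] <- 0
  calibratedImage(.clamp01(img), fovMM = params@fovMM,
                  modality = params@modality)
}

#' Rasterize the exact network centerlines as a 1-px skeleton
#'
#' The oracle counterpart of the full segmentation chain: draws each
#' centerline polyline onto the requested grid with Bresenham line
#' rasterization, over the central `fovMM` window of the network FOV (the
#' same windowing convention as [renderModality()]).
#'
#' @param net a [GroundTruthNetwork-class].
#' @param gridPx integer(2) (width, height) of the target grid in pixels.
#' @param fovMM numeric(2) physical extent of the target grid in mm.
#' @return A [SkeletonMask-class].
#' @examples
#' net <- generateNetwork(syntheticConfig(seed = 3, nRoots = 2,
#'                                        fovMM = c(4, 4)))
#' sk <- groundTruthSkeleton(net, gridPx = c(100, 100), fovMM = c(4, 4))
#' sk
#' @export
groundTruthSkeleton <- function(net, gridPx, fovMM) {
  stopifnot(is(net, "GroundTruthNetwork"),
            length(gridPx) == 2L, all(gridPx >= 1),
            length(fovMM) == 2L, all(fovMM > 0))
  wPx <- as.integer(gridPx[1L]); hPx <- as.integer(gridPx[2L])
  mask <- matrix(FALSE, hPx, wPx)
  mmpp <- c(fovMM[1L] / wPx, fovMM[2L] / hPx)
  off <- (net@fovMM - fovMM) / 2
  toPx <- function(p) c(
    min(wPx, max(1L, floor(p[1L] / mmpp[1L]) + 1L)),
    min(hPx, max(1L, floor(p[2L] / mmpp[2L]) + 1L)))
  for (poly in net@segments) {
    for (e in seq_len(nrow(poly) - 1L)) {
      cl <- .clipSegment(poly[e, ] - off, poly[e + 1L, ] - off,
                         fovMM[1L], fovMM[2L])
      if (is.null(cl)) next
      a <- toPx(cl[1L, ]); b <- toPx(cl[2L, ])
      # Bresenham walk from a to b in (col, row)
      x <- a[1L]; y <- a[2L]
      dx <- abs(b[1L] - x); dy <- -abs(b[2L] - y)
      sx <- sign(b[1L] - x); sy <- sign(b[2L] - y)
      err <- dx + dy
      repeat {
        mask[y, x] <- TRUE
        if (x == b[1L] && y == b[2L]) break
        e2 <- 2 * err
        if (e2 >= dy) { err <- err + dy; x <- x + sx }
        if (e2 <= dx) { err <- err + dx; y <- y + sy }
      }
    }
  }
  skeletonMask(.thinCleanup(mask), provenance = "ground_truth")
}
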