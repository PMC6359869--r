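#' Box-counting configuration
#'
#' Defaults follow the fractal-analysis settings used for conjunctival
#' skeletons: largest box side 104 px and 15 box sizes on a geometric
#' schedule down to 2 px ("increment of box sizes" is read as the number of
#' sizes; a linear schedule is selectable). The grid is anchored at the
#' image's top-left corner; optionally the count per size is minimized over
#' several regularly spaced grid origins (off by default for determinism).
#'
#' @param largestBoxPx side length of the largest box, px.
#' @param nSizes number of box sizes (>= 3; the log-log fit needs >= 3
#'   points).
#' @param schedule `"geometric"` or `"linear"` spacing of sizes.
#' @param gridOffsets number of grid origins searched per size (>= 1).
#' @return A list of class `"BoxCountConfig"`.
#' @export
boxCountConfig <- function(largestBoxPx = 104L, nSizes = 15L,
                           schedule = c("geometric", "linear"),
                           gridOffsets = 1L) {
  schedule <- match.arg(schedule)
  if (nSizes < 3L) stop("nSizes must be >= 3 (the fit needs >= 3 points)")
  if (largestBoxPx < 2L) stop("largestBoxPx must be >= 2")
  if (gridOffsets < 1L) stop("gridOffsets must be >= 1")
  structure(list(largestBoxPx = as.integer(largestBoxPx),
                 nSizes = as.integer(nSizes), schedule = schedule,
                 gridOffsets = as.integer(gridOffsets)),
            class = "BoxCountConfig")
}

#' Compute the box-size schedule
#'
#' Generates `nSizes` strictly decreasing integer box sides from
#' `largestBoxPx` down to 2 px: a geometric (or linear) progression, rounded
#' to integers, with duplicates collapsed and backfilled with the nearest
#' unused integers so the requested number of distinct sizes is kept
#' whenever the integer range allows.
#'
#' @param cfg a [boxCountConfig()].
#' @return Integer vector of strictly decreasing box sides.
#' @examples
#' boxSizeSchedule(boxCountConfig(8, 3))    # 8 4 2
#' boxSizeSchedule(boxCountConfig())        # 15 sizes, 104 .. 2
#' @export
boxSizeSchedule <- function(cfg = boxCountConfig()) {
  stopifnot(inherits(cfg, "BoxCountConfig"))
  smax <- cfg$largestBoxPx; n <- cfg$nSizes
  raw <- if (cfg$schedule == "geometric")
    smax * ((2 / smax)^(1 / (n - 1L)))^(0:(n - 1L))      # smax .. 2
  else seq(smax, 2, length.out = n)
  sizes <- unique(pmax(2L, as.integer(round(raw))))
  # backfill: walk the schedule enforcing strict decrease where possible
  out <- integer(0)
  prev <- smax + 1L
  for (s in sizes) {
    s <- min(s, prev - 1L)
    if (s < 2L) break
    out <- c(out, s)
    prev <- s
  }
  # if rounding collapsed sizes, backfill unused integers between the gaps
  while (length(out) < n) {
    gaps <- setdiff(seq(2L, smax), out)
    if (!length(gaps)) break
    # insert the unused size closest (in log space) to the thinnest gap
    target <- gaps[which.max(vapply(gaps, function(g)
      min(abs(log(g) - log(out))), numeric(1)))]
    out <- sort(unique(c(out, target)), decreasing = TRUE)
  }
  out
}

#' Skeleton pixel-percentage density
#'
#' The fraction of image pixels lying on vessel centerlines, in percent:
#' `100 * foreground / total`. With 1-px skeletons this weights every vessel
#' equally regardless of caliber.
#'
#' @param skel a [BinaryMask-class] (conventionally a
#'   [SkeletonMask-class]).
#' @return Numeric percentage in [0, 100].
#' @export
densityPercent <- function(skel) {
  stopifnot(is(skel, "BinaryMask"))
  100 * sum(skel@mask) / length(skel@mask)
}

# Occupied-box count for one size, top-left-anchored grid with partial edge
# boxes included; origin may be displaced by (offR, offC) >= 0.
.countBoxes <- function(idxR, idxC, s, offR = 0L, offC = 0L) {
  br <- (idxR + offR) %/% s
  bc <- (idxC + offC) %/% s
  length(unique(br * (max(bc) + 1L) + bc))
}

#' Box counting and fractal dimension of a skeleton
#'
#' For each box side s in the schedule, tiles the image from the top-left
#' origin with s x s boxes (partial boxes at the edges included) and counts
#' the boxes containing at least one foreground pixel. When
#' `cfg$gridOffsets > 1`, the minimum count over that many regularly spaced
#' grid origins is taken. The box-counting dimension Dbox is the
#' ordinary-least-squares slope of log N(s) against log(1/s), with the fit's
#' R-squared reported as a diagnostic.
#'
#' @param skel a non-empty [BinaryMask-class].
#' @param cfg a [boxCountConfig()].
#' @return A [BoxCountResult-class].
#' @examples
#' m <- matrix(FALSE, 128, 128); m[64, ] <- TRUE   # a line: Dbox ~ 1
#' dbox(boxCount(binaryMask(m), boxCountConfig(32, 8)))
#' @export
boxCount <- function(skel, cfg = boxCountConfig()) {
  stopifnot(is(skel, "BinaryMask"))
  m <- skel@mask
  if (!any(m)) stop("Dbox undefined for empty mask")
  if (cfg$largestBoxPx > min(dim(m)))
    stop("grid too small to host the largest box")
  sizes <- boxSizeSchedule(cfg)
  idx <- which(m) - 1L
  idxR <- idx %% nrow(m)
  idxC <- idx %/% nrow(m)
  counts <- vapply(sizes, function(s) {
    if (cfg$gridOffsets == 1L) return(.countBoxes(idxR, idxC, s))
    offs <- unique(as.integer(round(seq(0, s - 1,
                                        length.out = cfg$gridOffsets))))
    min(vapply(offs, function(o) .countBoxes(idxR, idxC, s, o, o), numeric(1)))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(counts))
  slope <- unname(fit$coefficients[2L])
  ss <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (ss > 0) 1 - sum(fit$residuals^2) / ss else 1
  new("BoxCountResult", sizesPx = as.numeric(sizes), counts = counts,
      dbox = slope, rSquared = r2,
      intercept = unname(fit$coefficients[1L]))
}

#' Bundle both density readouts into one record
#'
#' @param skel a [SkeletonMask-class] (or [BinaryMask-class]).
#' @param cfg a [boxCountConfig()].
#' @param subject,eye,modality provenance fields for the record.
#' @return A one-row data.frame with columns `subject`, `eye`, `modality`,
#'   `density_percent`, `dbox`, `r_squared`.
#' @export
quantifySkeleton <- function(skel, cfg = boxCountConfig(), subject = NA,
                             eye = NA_character_, modality = NA_character_) {
  bc <- boxCount(skel, cfg)
  data.frame(subject = subject, eye = eye, modality = modality,
             density_percent = densityPercent(skel), dbox = bc@dbox,
             r_squared = bc@rSquared, stringsAsFactors = FALSE)
}
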