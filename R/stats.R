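#' Paired comparison of two modalities (repeated-measures / paired t)
#'
#' Two-level within-unit repeated-measures ANOVA of one measurement taken by
#' two devices on the same units, together with the equivalent paired t-test
#' (with two within-unit levels F equals t squared and the p-values
#' coincide). Differences are oriented `a - b`. When the differences have
#' zero variance but a nonzero mean — the two devices differ by an exact
#' constant — the statistic is unbounded; this is reported as `p = 0` with
#' `degenerate = TRUE` rather than an error.
#'
#' @param a,b numeric vectors of paired measurements, length >= 3.
#' @param unitIds optional unit identifiers (one pair per unit).
#' @return A list with `meanA`, `sdA`, `meanB`, `sdB`, `statisticT`,
#'   `statisticF`, `pValue`, `nPairs`, `meanDiff`, `degenerate`.
#' @examples
#' pairedCompare(c(1, 2, 3, 4), c(2, 3, 5, 6))   # t ~ -5.196, p ~ 0.0139
#' @export
pairedCompare <- function(a, b, unitIds = seq_along(a)) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unitIds) != n) stop("one unit id per pair required")
  if (anyDuplicated(unitIds)) stop("one (a, b) pair per unit required")
  d <- a - b
  sdD <- stats::sd(d)
  base <- list(meanA = mean(a), sdA = stats::sd(a), meanB = mean(b),
               sdB = stats::sd(b), nPairs = n, meanDiff = mean(d))
  if (sdD == 0) {
    if (mean(d) == 0)
      return(c(base, list(statisticT = 0, statisticF = 0, pValue = 1,
                          degenerate = FALSE)))
    return(c(base, list(statisticT = sign(mean(d)) * Inf, statisticF = Inf,
                        pValue = 0, degenerate = TRUE)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  # the equivalent two-level repeated-measures ANOVA, for the F form
  df <- data.frame(y = c(a, b),
                   device = factor(rep(c("a", "b"), each = n)),
                   unit = factor(rep(unitIds, 2L)))
  av <- summary(stats::aov(y ~ device + Error(unit / device), data = df))
  tab <- av[["Error: unit:device"]][[1L]]
  Fv <- tab["device", "F value"]
  pF <- tab["device", "Pr(>F)"]
  c(base, list(statisticT = unname(tt$statistic), statisticF = unname(Fv),
               pValue = unname(pF), degenerate = FALSE))
}

#' Pearson correlation with significance test
#'
#' Sample correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A list with `r`, `pValue`, `n`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    p <- unname(ct$p.value)
  }
  list(r = unname(r), pValue = p, n = length(x))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference between two paired measurement methods with the 95%
#' limits of agreement at mean +/- 1.96 times the sample (n - 1) standard
#' deviation of the differences. Differences are oriented `a - b`.
#'
#' @param a,b numeric vectors of paired measurements, length >= 2.
#' @return A list of class `"AgreementStats"` with `meanDiff`, `sdDiff`,
#'   `loaLow`, `loaHigh`, `n`, plus the per-pair `means` and `diffs` used
#'   for plotting.
#' @seealso [plotBlandAltman()]
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  structure(list(meanDiff = m, sdDiff = s, loaLow = m - 1.96 * s,
                 loaHigh = m + 1.96 * s, n = n,
                 means = (a + b) / 2, diffs = d),
            class = "AgreementStats")
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with horizontal
#' lines at the mean difference (solid) and the 95% limits of agreement
#' (dashed).
#'
#' @param ba an object from [blandAltman()].
#' @param xlab,ylab,main plot annotation.
#' @return `ba`, invisibly.
#' @export
plotBlandAltman <- function(ba, xlab = "Mean of methods",
                            ylab = "Difference (A - B)",
                            main = "Bland-Altman") {
  stopifnot(inherits(ba, "AgreementStats"))
  pad <- max(1e-9, 0.2 * max(abs(c(ba$diffs, ba$loaLow, ba$loaHigh))))
  graphics::plot(ba$means, ba$diffs, pch = 19, xlab = xlab, ylab = ylab,
                 main = main,
                 ylim = range(c(ba$diffs, ba$loaLow, ba$loaHigh)) +
                   c(-pad, pad))
  graphics::abline(h = ba$meanDiff, lty = 1)
  graphics::abline(h = c(ba$loaLow, ba$loaHigh), lty = 2)
  invisible(ba)
}

#' Sample mean and standard deviation
#'
#' The mean +/- SD summary used throughout reporting; SD uses the n - 1
#' denominator.
#'
#' @param values numeric vector, length >= 2.
#' @return A named numeric vector `c(mean, sd)`.
#' @export
meanSD <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  c(mean = mean(values), sd = stats::sd(values))
}
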