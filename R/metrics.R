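#' Normalized mean squared error
#'
#' `|estimate - reference|^2 / |reference|^2`, the standard figure of merit
#' for comparing reconstructed diffusion signals against a reference.
#'
#' @param estimate,reference Equal-length numeric vectors (reference not
#'   all zero).
#' @return Dimensionless NMSE (0 for a perfect reconstruction, 1 for an
#'   all-zero estimate).
#' @export
nmse <- function(estimate, reference) {
  if (length(estimate) != length(reference))
    stop("estimate and reference must have equal length")
  den <- sum(reference^2)
  if (den == 0) stop("reference must not be all zero")
  sum((estimate - reference)^2) / den
}

#' Per-b-value MSE between two volume sets
#'
#' Mean squared voxel difference between corresponding volumes of two 4D
#' arrays, aggregated per b-value bin - the comparison used to judge
#' distortion-correction quality between forward and reverse
#' phase-encoding acquisitions.
#'
#' @param setA,setB 4D arrays with matching dimensions.
#' @param bvals One b-value per volume.
#' @param bins Optional numeric break points (passed to [cut()]); by
#'   default each distinct b-value is its own bin.
#' @param mask Optional 3D logical mask.
#' @return Data frame with `b` (bin label or b-value), `mse`, `nVolumes`.
#' @export
mseByBvalue <- function(setA, setB, bvals, bins = NULL, mask = NULL) {
  if (!all(dim(setA) == dim(setB)))
    stop("volume sets must have identical dimensions")
  if (dim(setA)[4] != length(bvals))
    stop("mismatched volume counts: ", dim(setA)[4], " volumes vs ",
         length(bvals), " b-values")
  grp <- if (is.null(bins)) factor(bvals) else cut(bvals, breaks = bins)
  msePerVol <- vapply(seq_along(bvals), function(v) {
    d <- setA[, , , v] - setB[, , , v]
    if (!is.null(mask)) d <- d[mask]
    mean(d^2)
  }, 0)
  out <- data.frame(
    b = levels(grp),
    mse = as.numeric(tapply(msePerVol, grp, mean)),
    nVolumes = as.integer(table(grp)))
  rownames(out) <- NULL
  out
}

#' Angular cross-correlation of two spherical functions
#'
#' Normalized inner product of real even spherical-harmonic coefficient
#' vectors with the l = 0 term excluded (two isotropic functions would
#' otherwise correlate perfectly):
#' `sum_{l>0} u_lm v_lm / sqrt(sum u^2 * sum v^2)`. Symmetric and invariant
#' to positive scaling of either argument.
#'
#' @param f,g Coefficient vectors from [shFit()] with equal order.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   function has no anisotropic part.
#' @export
acc <- function(f, g) {
  idxF <- attr(f, "indices"); idxG <- attr(g, "indices")
  if (is.null(idxF) || is.null(idxG) || nrow(idxF) != nrow(idxG))
    stop("f and g must be SH coefficient vectors of the same order")
  keep <- idxF$l > 0
  u <- as.numeric(f)[keep]; v <- as.numeric(g)[keep]
  nu <- sum(u^2); nv <- sum(v^2)
  if (nu == 0 || nv == 0) {
    warning("zero anisotropic part; ACC undefined")
    return(NA_real_)
  }
  sum(u * v) / sqrt(nu * nv)
}

# Minimum-total-angle assignment between two direction line sets
# (exact brute force over permutations; peak sets are small).
matchPeakLines <- function(d1, d2) {
  n1 <- nrow(d1); n2 <- nrow(d2)
  swap <- n1 > n2
  if (swap) { tmp <- d1; d1 <- d2; d2 <- tmp; tmp <- n1; n1 <- n2; n2 <- tmp }
  angMat <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    angMat[i, j] <- lineAngleDeg(d1[i, ], d2[j, ])
  if (n1 == 0L) return(list(angles = numeric(0), pairs = cbind(integer(0), integer(0))))
  perms <- permutationsOf(n2, n1)
  tot <- apply(perms, 1L, function(p) sum(angMat[cbind(seq_len(n1), p)]))
  best <- perms[which.min(tot), ]
  ang <- angMat[cbind(seq_len(n1), best)]
  pairs <- if (swap) cbind(best, seq_len(n1)) else cbind(seq_len(n1), best)
  list(angles = ang, pairs = pairs)
}

# All ordered selections of k items from n (n^k small for peak sets).
permutationsOf <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), 1L, 0L))
  out <- matrix(seq_len(n), ncol = 1L)
  for (j in seq_len(k - 1L)) {
    out <- do.call(rbind, lapply(seq_len(n), function(v) {
      keep <- rowSums(out == v) == 0L
      cbind(out[keep, , drop = FALSE], v)
    }))
  }
  out
}

#' Mean angular difference between matched peak directions
#'
#' Peaks of the two sets are matched by the minimum-total-angle assignment
#' over direction lines (angle = arccos |u . v|); the mean matched angle is
#' returned. With unequal peak counts, matching covers the smaller count
#' and the result is flagged via the `"cardinalityMismatch"` attribute.
#'
#' @param p1,p2 Non-empty [PeakSet-class] objects.
#' @return Mean matched angle in degrees.
#' @export
angularPeakDifference <- function(p1, p2) {
  if (!nPeaks(p1) || !nPeaks(p2)) stop("peak sets must be non-empty")
  m <- matchPeakLines(directions(p1), directions(p2))
  out <- mean(m$angles)
  attr(out, "cardinalityMismatch") <- nPeaks(p1) != nPeaks(p2)
  out
}

#' Deviation between crossing angles of the two dominant peaks
#'
#' `|angle(p1_1, p1_2) - angle(p2_1, p2_2)|` for the two highest-amplitude
#' peaks of each set (line angles, degrees). Requires both sets to hold at
#' least two peaks.
#'
#' @param p1,p2 [PeakSet-class] objects with >= 2 peaks.
#' @return Absolute crossing-angle deviation, degrees.
#' @export
crossingAngleDeviation <- function(p1, p2) {
  if (nPeaks(p1) < 2L || nPeaks(p2) < 2L)
    stop("both peak sets need >= 2 peaks for a crossing angle")
  d1 <- directions(p1); d2 <- directions(p2)
  abs(lineAngleDeg(d1[1, ], d1[2, ]) - lineAngleDeg(d2[1, ], d2[2, ]))
}

#' Minimum crossing angle at a prevalence level
#'
#' The smallest angle `a` such that at least `prevalence` of the voxels
#' have a crossing angle `<= a` (empirical quantile, lower interpolation) -
#' e.g. the minimum crossing angle occurring in at least 1% of white-matter
#' voxels.
#'
#' @param crossingAngles Per-voxel crossing angles, degrees (non-empty).
#' @param prevalence Fraction in `(0, 1]` (default 0.01).
#' @return Angle in degrees.
#' @export
minCrossingAngle <- function(crossingAngles, prevalence = 0.01) {
  if (!length(crossingAngles)) stop("empty crossing-angle input")
  if (prevalence <= 0 || prevalence > 1)
    stop("prevalence must lie in (0, 1]")
  s <- sort(crossingAngles)
  s[ceiling(prevalence * length(s))]
}

#' Fiber count detected by both schemes
#'
#' The minimum, over the two peak sets, of the number of peaks whose
#' relative fraction exceeds `fractionThreshold`, capped at 3 - the rule
#' for counting fibers reliably detected by two acquisition schemes.
#'
#' @param p1,p2 [PeakSet-class] objects.
#' @param fractionThreshold Fraction threshold in `[0, 1]` (default 0.1).
#' @return Integer in `{0, 1, 2, 3}`.
#' @export
fiberCount <- function(p1, p2, fractionThreshold = 0.1) {
  if (fractionThreshold < 0 || fractionThreshold > 1)
    stop("fractionThreshold must lie in [0, 1]")
  n1 <- sum(p1@peaks$fraction > fractionThreshold)
  n2 <- sum(p2@peaks$fraction > fractionThreshold)
  min(min(n1, n2), 3L)
}

#' Intraclass correlation coefficient (one-way random, single measures)
#'
#' ICC(1,1) from the one-way ANOVA decomposition of paired scan/rescan
#' values: `(MSB - MSW) / (MSB + (k-1) MSW)` with k = 2 measurements per
#' subject. Values near 1 indicate that between-subject differences
#' dominate measurement noise.
#'
#' @param scan,rescan Paired per-subject values (length n >= 2).
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(scan, rescan) {
  if (length(scan) != length(rescan)) stop("scan/rescan must be paired")
  n <- length(scan)
  if (n < 2L) stop("need >= 2 subjects")
  k <- 2
  m <- cbind(scan, rescan)
  subjMean <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((subjMean - grand)^2) / (n - 1)
  msw <- sum((m - subjMean)^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Within-subject coefficient of variation
#'
#' `sqrt(mean within-subject variance) / grand mean * 100`, with the
#' within-subject variance of a scan/rescan pair taken as `d^2 / 2` for the
#' paired difference d (the Bland-Altman repeatability formulation).
#'
#' @param scan,rescan Paired per-subject values.
#' @return wsCV in percent (>= 0).
#' @export
wscv <- function(scan, rescan) {
  if (length(scan) != length(rescan)) stop("scan/rescan must be paired")
  grand <- mean(c(scan, rescan))
  if (grand == 0) stop("zero grand mean: wsCV undefined")
  wsVar <- mean((scan - rescan)^2 / 2)
  sqrt(wsVar) / grand * 100
}
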