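#' Diffusion propagator from fully sampled q-space signals
#'
#' Inverts fully sampled attenuations to the displacement-space propagator
#' by the centred discrete Fourier transform, clamps negative ringing to
#' zero and normalizes to unit mass. Input may be a full cubic array
#' (centred order, e.g. from [simulateCubeSignal()]) or a vector over the
#' grid's lattice points (in `gridPoints()` order; cube locations outside
#' the truncation sphere are set to zero).
#'
#' @param values 3D array `(2r+1)^3` or numeric vector of length
#'   `nrow(gridPoints(grid))`.
#' @param grid The [CartesianQGrid-class].
#' @param meta Optional [ProtocolMeta-class]; enables physical (mm) units.
#' @return A [Propagator-class].
#' @export
propagatorFromSignals <- function(values, grid, meta = NULL) {
  N <- 2L * grid@radius + 1L
  if (is.array(values) && length(dim(values)) == 3L) {
    cube <- values
    if (!all(dim(cube) == N)) stop("cube extent must match the grid")
  } else {
    if (length(values) != nrow(grid@points))
      stop("need one value per grid point")
    cube <- array(0, rep(N, 3L))
    pts <- grid@points + grid@radius + 1L
    cube[cbind(pts[, 1], pts[, 2], pts[, 3])] <- values
  }
  if (anyNA(cube)) stop("NaN/NA in signal values")
  pu <- centeredIdft(cube)                 # real up to numerical noise
  finalizePropagator(pu, grid, meta, info = list(method = "direct-fft"))
}

# Centred displacement coordinates (grid units) along one axis.
centeredAxis <- function(N) seq_len(N) - (N %/% 2L) - 1L

setMethod("msd", "Propagator", function(p) {
  v <- p@values
  s <- sum(v)
  if (abs(s - 1) > 1e-6) {
    warning("propagator mass != 1; normalizing internally")
    v <- v / s
  }
  ax <- centeredAxis(dim(v)[1])
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  m <- sum(v * r2)
  list(grid = m, mm2 = m * p@spacingMm^2)
})

setMethod("rtop", "Propagator", function(p) {
  v <- p@values
  s <- sum(v)
  if (s > 0 && abs(s - 1) > 1e-6) v <- v / s
  ctr <- dim(v)[1] %/% 2L + 1L
  r <- v[ctr, ctr, ctr]                    # probability mass at the origin
  list(grid = r, gridCbrt = r^(1 / 3),
       mm = r / p@spacingMm^3, mmCbrt = (r / p@spacingMm^3)^(1 / 3))
})

# Trilinear interpolation of a centred cube at continuous grid-unit
# coordinates (n x 3 matrix); zero outside the array.
trilinear <- function(cube, xyz) {
  N <- dim(cube)[1]
  ctr <- N %/% 2L + 1L
  pos <- xyz + ctr
  out <- numeric(nrow(pos))
  inside <- rowSums(pos >= 1 & pos <= N) == 3L
  if (!any(inside)) return(out)
  pos <- pos[inside, , drop = FALSE]
  lo <- pmax(pmin(floor(pos), N - 1L), 1L)
  fr <- pos - lo
  acc <- numeric(nrow(pos))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * cube[cbind(lo[, 1] + dx, lo[, 2] + dy, lo[, 3] + dz)]
  }
  out[inside] <- acc
  out
}

setMethod("dodf", "Propagator",
  function(p, directions = NULL, rMax = NULL, nSubdiv = 3L) {
    tess <- NULL
    if (is.null(directions)) {
      tess <- sphereTessellation(nSubdiv)
      directions <- tess$vertices
    }
    half <- dim(p@values)[1] %/% 2L
    if (is.null(rMax)) rMax <- p@gridRadius
    if (rMax > half) {
      warning("rMax exceeds the grid half-extent; clipping")
      rMax <- half
    }
    rs <- seq(0, rMax, by = 0.5)
    vals <- numeric(nrow(directions))
    for (k in seq_along(rs)) {
      r <- rs[k]
      w <- if (k == 1L || k == length(rs)) 0.5 else 1   # trapezoid
      # antipodal average enforced by sampling both hemispheres
      vals <- vals + w * 0.5 * r^2 *
        (trilinear(p@values, directions * r) +
         trilinear(p@values, -directions * r)) / 2
    }
    faces <- if (is.null(tess)) matrix(0L, 0L, 3L) else tess$faces
    new("DODF", directions = directions, values = pmax(vals, 0),
        faces = faces)
  })

setMethod("extractPeaks", "DODF",
  function(odf, relThreshold = 0.1, minSep = 25) {
    if (relThreshold < 0 || relThreshold > 1)
      stop("relThreshold must lie in [0, 1]")
    empty <- new("PeakSet", peaks = data.frame(
      dx = numeric(0), dy = numeric(0), dz = numeric(0),
      amplitude = numeric(0), fraction = numeric(0)))
    if (!length(odf@values) || max(odf@values) <= 0) return(empty)
    if (!nrow(odf@faces))
      stop("peak extraction requires a tessellation with faces")
    adj <- faceAdjacency(odf@faces, nrow(odf@directions))
    isMax <- vapply(seq_along(odf@values), function(i)
      all(odf@values[i] >= odf@values[adj[[i]]]), TRUE)
    cand <- which(isMax)
    cand <- cand[order(odf@values[cand], decreasing = TRUE)]
    sel <- integer(0)
    for (i in cand) {
      u <- odf@directions[i, ]
      ok <- TRUE
      for (j in sel)
        if (lineAngleDeg(u, odf@directions[j, ]) < minSep) { ok <- FALSE; break }
      if (ok) sel <- c(sel, i)
    }
    if (!length(sel)) return(empty)
    amp <- odf@values[sel]
    frac <- amp / sum(amp)
    keep <- frac > relThreshold
    pk <- data.frame(dx = odf@directions[sel, 1],
                     dy = odf@directions[sel, 2],
                     dz = odf@directions[sel, 3],
                     amplitude = amp, fraction = frac)[keep, , drop = FALSE]
    rownames(pk) <- NULL
    new("PeakSet", peaks = pk)
  })

#' @describeIn directions Peak directions (one row per peak).
#' @export
setMethod("directions", "PeakSet", function(x)
  as.matrix(x@peaks[, c("dx", "dy", "dz")]))

#' Number of peaks in a PeakSet
#'
#' @param x A [PeakSet-class].
#' @return Integer.
#' @export
nPeaks <- function(x) nrow(x@peaks)
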