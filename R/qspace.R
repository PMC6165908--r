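#' Construct a ProtocolMeta object
#'
#' @param te,tr Echo and repetition time, ms.
#' @param Delta,delta Gradient pulse separation and duration, ms.
#' @param nB0 Number of interleaved b = 0 volumes.
#' @return A [ProtocolMeta-class].
#' @examples
#' protocolMeta(te = 101.4, tr = 5300, Delta = 49.5, delta = 19.7, nB0 = 8)
#' @export
protocolMeta <- function(te, tr, Delta, delta, nB0 = 0L) {
  new("ProtocolMeta", te = as.numeric(te), tr = as.numeric(tr),
      Delta = as.numeric(Delta), delta = as.numeric(delta),
      nB0 = as.integer(nB0))
}

#' Effective diffusion time
#'
#' tau = Delta - delta/3, in seconds.
#'
#' @param meta A [ProtocolMeta-class].
#' @return Effective diffusion time in seconds.
#' @export
diffusionTime <- function(meta) {
  stopifnot(is(meta, "ProtocolMeta"))
  (meta@Delta - meta@delta / 3) / 1000
}

#' Sequence timing of the reference CS-DSI and 3-shell protocols
#'
#' Convenience constructors for the two protocol metadata sets used
#' throughout: CS-DSI (TE/TR = 101.4/5300 ms, Delta = 49.5 ms,
#' delta = 19.7 ms, 8 interleaved b = 0 scans) and 3-shell HARDI
#' (TE/TR = 90/4800 ms, Delta = 43.9 ms, delta = 14 ms, 14 b = 0 scans).
#'
#' @return A [ProtocolMeta-class].
#' @export
csDsiMeta <- function() protocolMeta(101.4, 5300, 49.5, 19.7, 8L)

#' @rdname csDsiMeta
#' @export
multishellMeta <- function() protocolMeta(90, 4800, 43.9, 14, 14L)

#' Build the truncated-sphere Cartesian q-space grid
#'
#' Enumerates every integer lattice point with squared norm <= radius^2 in
#' lexicographic (qz, qy, qx) order and attaches the quadratic b-value
#' mapping b = bMax * |q|^2 / radius^2. Radius 5 yields the standard
#' 11 x 11 x 11 DSI grid: 515 points, 258 antipodally unique, 257 unique
#' diffusion-weighted.
#'
#' @param radius Integer lattice radius (>= 0).
#' @param bMax b-value at the sphere boundary, s/mm^2.
#' @return A [CartesianQGrid-class].
#' @examples
#' g <- buildGrid(5L, 6800)
#' nrow(gridPoints(g))          # 515
#' sum(uniquePoints(g))         # 258
#' @export
buildGrid <- function(radius, bMax = 6800) {
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("radius must be a single non-negative integer")
  radius <- as.integer(radius)
  ax <- seq.int(-radius, radius)
  pts <- as.matrix(expand.grid(qx = ax, qy = ax, qz = ax,
                               KEEP.OUT.ATTRS = FALSE))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  ord <- order(pts[, "qz"], pts[, "qy"], pts[, "qx"])
  pts <- pts[ord, , drop = FALSE]
  storage.mode(pts) <- "integer"
  rownames(pts) <- NULL
  new("CartesianQGrid", radius = radius, bMax = as.numeric(bMax),
      points = pts)
}

#' Lattice points of a grid
#'
#' @param grid A [CartesianQGrid-class].
#' @return Integer matrix (n x 3) in canonical (qz, qy, qx)-lexicographic
#'   order.
#' @export
gridPoints <- function(grid) {
  stopifnot(is(grid, "CartesianQGrid"))
  grid@points
}

#' @describeIn bValues b-value per lattice point.
#' @export
setMethod("bValues", "CartesianQGrid", function(x) {
  if (x@radius == 0L) return(rep(0, nrow(x@points)))
  x@bMax * rowSums(x@points^2) / x@radius^2
})

#' @describeIn bValues b-value per scheme entry.
#' @export
setMethod("bValues", "SamplingScheme", function(x) x@entries$bval)

#' @describeIn directions Direction per scheme entry (zero rows at b = 0).
#' @export
setMethod("directions", "SamplingScheme", function(x)
  as.matrix(x@entries[, c("dx", "dy", "dz")]))

#' @describeIn nDwi Diffusion-weighted entry count of a scheme.
#' @export
setMethod("nDwi", "SamplingScheme", function(x, measuredOnly = FALSE) {
  keep <- x@entries$bval > 0
  if (measuredOnly) keep <- keep & x@entries$measured
  sum(keep)
})

# Antipodal representative test: first nonzero coordinate (x, y, z scan
# order) positive; the origin is its own representative.
antipodalRepresentative <- function(pts) {
  apply(pts, 1L, function(p) {
    i <- which(p != 0)[1L]
    if (is.na(i)) TRUE else p[i] > 0
  })
}

#' Antipodally unique lattice points
#'
#' Marks, for each lattice point, whether it is the canonical representative
#' of its antipodal pair (first nonzero coordinate positive; the origin is
#' self-paired).
#'
#' @param grid A [CartesianQGrid-class].
#' @return Logical vector over `gridPoints(grid)` rows.
#' @export
uniquePoints <- function(grid) {
  stopifnot(is(grid, "CartesianQGrid"))
  antipodalRepresentative(grid@points)
}

# Build a SamplingScheme data frame from grid rows.
schemeFromGridRows <- function(grid, rows, measured, protocolId, meta) {
  pts <- grid@points[rows, , drop = FALSE]
  b <- bValues(grid)[rows]
  nrm <- sqrt(rowSums(pts^2))
  d <- pts / ifelse(nrm > 0, nrm, 1)
  d[nrm == 0, ] <- 0
  entries <- data.frame(dx = d[, 1], dy = d[, 2], dz = d[, 3],
                        bval = b, qx = pts[, 1], qy = pts[, 2],
                        qz = pts[, 3], measured = measured)
  rownames(entries) <- NULL
  new("SamplingScheme", protocolId = protocolId, entries = entries,
      meta = meta)
}

setMethod("selectByBvalue", "CartesianQGrid", function(x, bLo, bHi) {
  if (bLo > bHi) stop("bLo must be <= bHi")
  b <- bValues(x)
  keep <- uniquePoints(x) & b > 0 & b >= bLo & b <= bHi
  if (!any(keep)) warning("empty b-value selection")
  schemeFromGridRows(x, which(keep), measured = rep(TRUE, sum(keep)),
                     protocolId = sprintf("grid-b%g-%g", bLo, bHi),
                     meta = NULL)
})

setMethod("selectByBvalue", "SamplingScheme", function(x, bLo, bHi) {
  if (bLo > bHi) stop("bLo must be <= bHi")
  e <- x@entries
  keep <- e$bval > 0 & e$bval >= bLo & e$bval <= bHi
  # drop antipodal duplicates among selected entries (direction lines +
  # equal b); unique schemes normally carry none.
  if (any(keep)) {
    idx <- which(keep)
    d <- as.matrix(e[idx, c("dx", "dy", "dz")])
    rep_ <- antipodalRepresentative(round(d, 9))
    sig <- apply(cbind(round(t(apply(d, 1L, function(v) {
      i <- which(abs(v) > 1e-12)[1L]
      if (!is.na(i) && v[i] < 0) -v else v
    })), 9), round(e$bval[idx], 6)), 1L, paste, collapse = "/")
    keep[idx[duplicated(sig)]] <- FALSE
  }
  if (!any(keep)) warning("empty b-value selection")
  out <- x
  out@entries <- e[keep, , drop = FALSE]
  rownames(out@entries) <- NULL
  out
})

# Group the antipodally unique nonzero grid rows into direction lines
# (collinear lattice points). Returns a list: per line the unit direction
# and the grid row indices ordered by radius.
gridDirectionLines <- function(grid) {
  rows <- which(uniquePoints(grid) & rowSums(grid@points^2) > 0)
  pts <- grid@points[rows, , drop = FALSE]
  prim <- t(apply(pts, 1L, function(p) {
    g <- 0L
    for (v in abs(p)) g <- gcd2(g, v)
    p / g
  }))
  key <- apply(prim, 1L, paste, collapse = ",")
  ord <- order(key, rowSums(pts^2))
  split(rows[ord], key[ord])
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Generate a compressed-sensing DSI sampling scheme
#'
#' Selects `ceiling(nUnique / accel)` of the grid's antipodally unique
#' diffusion-weighted samples to measure, one per antipodal pair: direction
#' lines are chosen by greedy farthest-point selection on the sphere (the
#' first line and radial positions drawn with the supplied seed), giving a
#' uniform angular distribution with random radial coverage, as in
#' CS-accelerated DSI acquisition design. Remaining grid samples are flagged
#' `measured = FALSE` and are to be recovered by [istaReconstruct()].
#'
#' At the standard radius-5 grid and acceleration 2.3 this yields 112
#' measured DWIs out of 257.
#'
#' @param grid A [CartesianQGrid-class].
#' @param accel Acceleration ratio in `[1, nUnique]`.
#' @param seed Integer seed (the scheme is deterministic given the seed).
#' @param meta Protocol metadata attached to the scheme (default
#'   [csDsiMeta()]); its `nB0` b = 0 entries are prepended.
#' @return A [SamplingScheme-class] covering all unique nonzero grid samples
#'   plus b = 0 entries, with `measured` marking the acquired subset.
#' @examples
#' s <- generateCsScheme(buildGrid(5L, 6800), accel = 2.3, seed = 1L)
#' nDwi(s, measuredOnly = TRUE)   # 112
#' @export
generateCsScheme <- function(grid, accel = 2.3, seed = 1L,
                             meta = csDsiMeta()) {
  stopifnot(is(grid, "CartesianQGrid"))
  uniqRows <- which(uniquePoints(grid) & rowSums(grid@points^2) > 0)
  nUnique <- length(uniqRows)
  if (accel < 1 || accel > nUnique)
    stop("accel must lie in [1, ", nUnique, "]")
  nMeas <- as.integer(ceiling(nUnique / accel))

  lines <- gridDirectionLines(grid)
  lineDirs <- t(vapply(lines, function(rws) {
    p <- grid@points[rws[1L], ]
    p / sqrt(sum(p^2))
  }, numeric(3)))

  nLines <- nrow(lineDirs)
  chosen <- withSeed(seed, {
    # greedy farthest-point over direction lines (line angle metric)
    pick <- sample.int(nLines, 1L)
    minAng <- rep(Inf, nLines)
    taken <- rep(FALSE, nLines)
    order_ <- integer(nLines)
    for (k in seq_len(nLines)) {
      order_[k] <- pick
      taken[pick] <- TRUE
      ang <- acos(pmin(1, abs(lineDirs %*% lineDirs[pick, ])))
      minAng <- pmin(minAng, ang)
      minAng[taken] <- -Inf
      if (k == nLines) break
      pick <- which.max(minAng)
    }
    # radial positions: walk the farthest-point order, drawing one unused
    # grid point per visited line uniformly at random, cycling through the
    # order until nMeas samples are collected.
    avail <- lapply(lines, identity)
    sel <- integer(0)
    li <- 1L
    while (length(sel) < nMeas) {
      ln <- order_[(li - 1L) %% nLines + 1L]
      li <- li + 1L
      pool <- avail[[ln]]
      if (length(pool) == 0L) {
        if (all(vapply(avail, length, 0L) == 0L)) break
        next
      }
      j <- if (length(pool) == 1L) 1L else sample.int(length(pool), 1L)
      sel <- c(sel, pool[j])
      avail[[ln]] <- pool[-j]
    }
    sel
  })

  measured <- uniqRows %in% chosen
  sch <- schemeFromGridRows(grid, uniqRows, measured,
                            protocolId = "cs-dsi", meta = meta)
  prependB0(sch, if (is.null(meta)) 0L else meta@nB0)
}

prependB0 <- function(scheme, nB0) {
  if (nB0 <= 0L) return(scheme)
  b0 <- data.frame(dx = 0, dy = 0, dz = 0, bval = 0,
                   qx = 0L, qy = 0L, qz = 0L, measured = TRUE)
  scheme@entries <- rbind(b0[rep(1L, nB0), ], scheme@entries)
  rownames(scheme@entries) <- NULL
  scheme
}
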