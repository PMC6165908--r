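#' Subdivided-icosahedron sphere tessellation
#'
#' Builds an antipodally symmetric triangulated sphere by repeated 4-fold
#' subdivision of the regular icosahedron with re-projection onto the unit
#' sphere: 12, 42, 162, 642, 2562, ... vertices at levels 0, 1, 2, 3, 4.
#'
#' @param nSubdiv Subdivision level (default 3, 642 vertices).
#' @return List with `vertices` (m x 3 unit vectors) and `faces` (f x 3
#'   integer triangles).
#' @export
sphereTessellation <- function(nSubdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalizeRows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(nSubdiv)) {
    mid <- new.env()
    nv <- nrow(v)
    newFaces <- matrix(0L, 0L, 3L)
    getMid <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "-")
      if (!is.null(mid[[key]])) return(mid[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    newFaces <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      newFaces[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newFaces
  }
  list(vertices = v, faces = f)
}

# Vertex adjacency list from a triangle matrix.
faceAdjacency <- function(faces, nVertices) {
  adj <- vector("list", nVertices)
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  sp <- split(edges[, 2], edges[, 1])
  for (k in names(sp)) adj[[as.integer(k)]] <- unique(sp[[k]])
  adj
}

# --- real even spherical harmonics -------------------------------------

# Index table (l, m) for even orders up to L.
shIndices <- function(L) {
  do.call(rbind, lapply(seq(0L, L, by = 2L), function(l)
    data.frame(l = l, m = seq(-l, l))))
}

#' Real even spherical-harmonic basis matrix
#'
#' Evaluates the real, antipodally symmetric (even-order) spherical-harmonic
#' basis at unit directions: for m = 0 the normalized Legendre term, for
#' m > 0 sqrt(2) * N_lm * P_lm(cos theta) * cos(m phi), for m < 0 the sine
#' counterpart. Orthonormal on the sphere.
#'
#' @param directions Unit-vector matrix (n x 3).
#' @param L Maximum (even) order, 4 or 8 typical.
#' @return Matrix n x nCoef with `attr(, "indices")` giving (l, m) per
#'   column.
#' @export
shBasis <- function(directions, L = 8L) {
  theta <- acos(pmin(1, pmax(-1, directions[, 3])))
  phi <- atan2(directions[, 2], directions[, 1])
  x <- cos(theta)
  idx <- shIndices(L)
  B <- matrix(0, nrow(directions), nrow(idx))
  for (l in unique(idx$l)) {
    P <- pracma::legendre(l, x)            # (l+1) x n, m = 0..l, CS phase
    if (l == 0L) P <- matrix(P, 1L)
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      col0 <- which(idx$l == l & idx$m == m)
      Pm <- P[m + 1L, ]
      if (m == 0L) {
        B[, col0] <- nrm * Pm
      } else {
        B[, col0] <- sqrt(2) * nrm * Pm * cos(m * phi)
        coln <- which(idx$l == l & idx$m == -m)
        B[, coln] <- sqrt(2) * nrm * Pm * sin(m * phi)
      }
    }
  }
  attr(B, "indices") <- idx
  B
}

#' Fit spherical-harmonic coefficients to samples of a spherical function
#'
#' Least-squares projection onto the real even basis of order `L`. Returns a
#' coefficient vector usable with [shEval()] and [acc()].
#'
#' @param values Function samples, one per direction.
#' @param directions Unit-vector matrix (n x 3).
#' @param L Maximum even order.
#' @return Numeric coefficient vector with `attr(, "indices")` and
#'   `attr(, "L")`.
#' @export
shFit <- function(values, directions, L = 8L) {
  B <- shBasis(directions, L)
  cf <- qr.solve(B, values)
  attr(cf, "indices") <- attr(B, "indices")
  attr(cf, "L") <- L
  cf
}

#' @rdname shFit
#' @param coefficients Coefficient vector from [shFit()].
#' @export
shEval <- function(coefficients, directions) {
  L <- attr(coefficients, "L")
  if (is.null(L)) L <- max(attr(coefficients, "indices")$l)
  drop(shBasis(directions, L) %*% as.numeric(coefficients))
}
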