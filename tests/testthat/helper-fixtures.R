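# Shared fixtures, built once per test run.

refGrid <- buildGrid(5L, 6800)
refCsScheme <- generateCsScheme(refGrid, accel = 2.3, seed = 101L)
refShellScheme <- generateMultishellScheme(
  rbind(c(1000, 30), c(2000, 40), c(3000, 50)), seed = 101L)

# Scheme subset plus one b = 0 row, ready for model fitting.
# (defined below after withB0)
withB0 <- function(scheme, sub) {
  b0 <- scheme@entries[scheme@entries$bval == 0, , drop = FALSE][1, ]
  sub@entries <- rbind(b0, sub@entries)
  rownames(sub@entries) <- NULL
  sub
}

# Build a SamplingScheme directly from directions and b-values.
schemeFromDirs <- function(dirs, bvals, protocolId = "test") {
  entries <- data.frame(dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                        bval = bvals, qx = NA_integer_, qy = NA_integer_,
                        qz = NA_integer_, measured = TRUE)
  entries[entries$bval == 0, c("dx", "dy", "dz")] <- 0
  new("SamplingScheme", protocolId = protocolId, entries = entries,
      meta = NULL)
}

# Multi-b shell scheme on tessellation directions (with one b = 0 row).
denseShellScheme <- function(bvals, nSubdiv = 1L) {
  dirs <- sphereTessellation(nSubdiv)$vertices
  keep <- csdsi:::antipodalRepresentative(round(dirs, 9))
  dirs <- dirs[keep, , drop = FALSE]
  d <- do.call(rbind, c(list(matrix(0, 1, 3)),
                        rep(list(dirs), length(bvals))))
  b <- c(0, rep(bvals, each = nrow(dirs)))
  schemeFromDirs(d, b)
}

# Gauss-Legendre x uniform-phi spherical product quadrature (exact for
# band-limited integrands far beyond SH order 8).
sphereQuadrature <- function(nTheta = 24L, nPhi = 48L) {
  gl <- pracma::gaussLegendre(nTheta, -1, 1)
  phis <- seq(0, 2 * pi, length.out = nPhi + 1L)[-(nPhi + 1L)]
  nodes <- do.call(rbind, lapply(seq_along(gl$x), function(i) {
    st <- sqrt(1 - gl$x[i]^2)
    cbind(st * cos(phis), st * sin(phis), gl$x[i])
  }))
  list(nodes = nodes,
       weights = rep(gl$w, each = nPhi) * (2 * pi / nPhi))
}

lineAngle <- csdsi:::lineAngleDeg

# Model-fit subsets of the reference CS scheme, reused across files.
dtSub <- withB0(refCsScheme, selectModelSubset(refCsScheme, "dt"))
kurtSub <- withB0(refCsScheme, selectModelSubset(refCsScheme, "kurtosis"))
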