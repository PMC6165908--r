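test_that("NMSE follows its definition and a brute-force sum oracle", {
  x <- c(1, 2, 3)
  expect_equal(nmse(x, x), 0)
  expect_equal(nmse(rep(0, 3), x), 1)
  set.seed(2)
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  brute <- 0
  den <- 0
  for (i in seq_along(a)) {
    brute <- brute + (a[i] - b[i])^2
    den <- den + b[i]^2
  }
  expect_equal(nmse(a, b), brute / den, tolerance = 1e-12)
  expect_error(nmse(a, rep(0, 50)), "all zero")
  expect_error(nmse(a, b[-1]), "equal length")
})

test_that("per-b MSE curves recover constructed noise levels", {
  dims <- c(6, 6, 6)
  bv <- rep(c(0, 1000, 2000), each = 4)
  nv <- length(bv)
  base <- array(stats::runif(prod(dims) * nv), c(dims, nv))
  expect_equal(mseByBvalue(base, base, bv)$mse, rep(0, 3))
  # constant offset c gives c^2 in every bin
  shifted <- base + 0.3
  expect_equal(mseByBvalue(base, shifted, bv)$mse, rep(0.09, 3))
  # bin-dependent noise sigma_b on both sets: MSE about 2 sigma_b^2
  sig <- c(0.05, 0.1, 0.2)[match(bv, c(0, 1000, 2000))]
  withr::with_seed(3, {
    nA <- array(stats::rnorm(length(base), 0,
                             rep(sig, each = prod(dims))), dim(base))
    nB <- array(stats::rnorm(length(base), 0,
                             rep(sig, each = prod(dims))), dim(base))
  })
  curve <- mseByBvalue(base + nA, base + nB, bv)
  expect_equal(curve$mse, 2 * c(0.05, 0.1, 0.2)^2, tolerance = 0.15)
  expect_error(mseByBvalue(base, base[, , , 1:3], bv),
               "identical dimensions")
  expect_error(mseByBvalue(base, base, bv[-1]), "mismatched")
})

test_that("angular cross-correlation matches a dense quadrature oracle", {
  dirs <- sphereTessellation(3L)$vertices
  f0 <- exp(-4 * (1 - dirs[, 1]^2))
  cf <- shFit(f0, dirs, 8L)
  expect_equal(acc(cf, cf), 1)
  for (angDeg in c(15, 30, 60, 90)) {
    ang <- angDeg * pi / 180
    R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
    # rotate the band-limited function itself
    cg <- shFit(shEval(cf, dirs %*% t(R)), dirs, 8L)
    q <- sphereQuadrature()
    fq <- shEval(cf, q$nodes); gq <- shEval(cg, q$nodes)
    fm <- sum(q$weights * fq) / (4 * pi)
    gm <- sum(q$weights * gq) / (4 * pi)
    oracle <- sum(q$weights * (fq - fm) * (gq - gm)) /
      sqrt(sum(q$weights * (fq - fm)^2) * sum(q$weights * (gq - gm)^2))
    expect_equal(acc(cf, cg), oracle, tolerance = 1e-3)
    # symmetry and positive-scale invariance
    expect_equal(acc(cf, cg), acc(cg, cf))
    c2 <- cf * 3.7
    attributes(c2) <- attributes(cf)
    expect_equal(acc(c2, cg), acc(cf, cg))
  }
  # disjoint (l, m) support is orthogonal
  idx <- attr(cf, "indices")
  u <- v <- numeric(length(cf))
  u[idx$l == 2][1] <- 1
  v[idx$l == 4][1] <- 1
  attributes(u) <- attributes(v) <- attributes(cf)
  expect_equal(acc(u, v), 0)
  # pure isotropic part is flagged undefined
  w <- numeric(length(cf)); w[idx$l == 0] <- 1
  attributes(w) <- attributes(cf)
  expect_warning(res <- acc(w, cf), "undefined")
  expect_true(is.na(res))
})

mkPeaks <- function(dirs, amps = NULL) {
  if (is.null(amps)) amps <- rev(seq_len(nrow(dirs)))
  o <- order(amps, decreasing = TRUE)
  dirs <- dirs[o, , drop = FALSE]; amps <- amps[o]
  new("PeakSet", peaks = data.frame(
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
    amplitude = amps, fraction = amps / sum(amps)))
}

test_that("peak matching equals the brute-force permutation oracle", {
  p1 <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(as.numeric(angularPeakDifference(p1, p1)), 0)
  # rotation by 10 degrees about z
  ang <- 10 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  p2 <- mkPeaks(directions(p1) %*% t(R))
  expect_equal(as.numeric(angularPeakDifference(p1, p2)), 10,
               tolerance = 1e-6)
  # scrambled three-peak sets vs exhaustive enumeration via pracma::perms
  set.seed(4)
  d1 <- csdsi:::normalizeRows(matrix(stats::rnorm(9), 3))
  d2 <- csdsi:::normalizeRows(matrix(stats::rnorm(9), 3))
  pa <- mkPeaks(d1); pb <- mkPeaks(d2)
  got <- as.numeric(angularPeakDifference(pa, pb))
  da <- directions(pa); db <- directions(pb)
  best <- Inf
  for (r in seq_len(nrow(pracma::perms(1:3)))) {
    pp <- pracma::perms(1:3)[r, ]
    tot <- sum(vapply(1:3, function(i) lineAngle(da[i, ], db[pp[i], ]), 0))
    best <- min(best, tot)
  }
  expect_equal(got, best / 3, tolerance = 1e-9)
  # cardinality mismatch is flagged, matched on the smaller count
  p3 <- mkPeaks(rbind(c(1, 0, 0)))
  res <- angularPeakDifference(p1, p3)
  expect_true(attr(res, "cardinalityMismatch"))
  expect_equal(as.numeric(res), 0)
})

test_that("crossing-angle deviation compares the two dominant peaks", {
  p1 <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0)))
  p2 <- mkPeaks(rbind(c(1, 0, 0),
                      c(cos(80 * pi / 180), sin(80 * pi / 180), 0)))
  expect_equal(crossingAngleDeviation(p1, p1), 0)
  expect_equal(crossingAngleDeviation(p1, p2), 10, tolerance = 1e-6)
  expect_error(crossingAngleDeviation(p1, mkPeaks(rbind(c(1, 0, 0)))),
               ">= 2")
})

test_that("minimum crossing angle is the lower empirical quantile", {
  expect_equal(minCrossingAngle(rep(90, 500), 0.01), 90)
  angles <- rep(seq(10, 90, by = 10), each = 20)
  expect_equal(minCrossingAngle(angles, 20 / 180), 10)
  set.seed(6)
  x <- stats::runif(777, 20, 90)
  # brute-force sort-and-scan oracle
  s <- sort(x)
  k <- 0
  repeat { k <- k + 1; if (k / length(s) >= 0.01) break }
  expect_equal(minCrossingAngle(x, 0.01), s[k])
  expect_error(minCrossingAngle(numeric(0)), "empty")
  expect_error(minCrossingAngle(x, 0), "prevalence")
})

test_that("fiber counts follow the dual-detection minimum rule", {
  a <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0)), c(5, 4))
  b <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0)), c(5, 4))
  expect_identical(fiberCount(a, b), 2L)
  c3 <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), c(5, 4, 3))
  c1 <- mkPeaks(rbind(c(1, 0, 0)), 5)
  expect_identical(fiberCount(c3, c1), 1L)
  # threshold rule against hand enumeration: fractions 0.5/0.3/0.2 and
  # 0.85/0.15 -> qualifying counts 3 and 2 at threshold 0.1 -> min 2
  d1 <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), c(50, 30, 20))
  d2 <- mkPeaks(rbind(c(1, 0, 0), c(0, 1, 0)), c(85, 15))
  expect_identical(fiberCount(d1, d2, 0.1), 2L)
  expect_identical(fiberCount(d1, d2, 0.25), 1L)
})

test_that("ICC and wsCV recover simulated variance components", {
  s <- c(1, 2, 3, 4)
  expect_equal(icc(s, s), 1)
  expect_equal(wscv(s, s), 0)
  # no between-subject variance: ICC near or below zero
  withr::with_seed(21, {
    iccs0 <- replicate(50, icc(stats::rnorm(100, 5, 0.1),
                               stats::rnorm(100, 5, 0.1)))
  })
  expect_lt(mean(iccs0), 0.05)
  # closed-form recovery at n = 200, 50 replicates
  sb <- 0.1; sw <- 0.03; mu <- 1
  nrep <- 50L; n <- 200L
  withr::with_seed(42, {
    iccs <- wscvs <- numeric(nrep)
    for (r in seq_len(nrep)) {
      subj <- stats::rnorm(n, mu, sb)
      s1 <- subj + stats::rnorm(n, 0, sw)
      s2 <- subj + stats::rnorm(n, 0, sw)
      iccs[r] <- icc(s1, s2)
      wscvs[r] <- wscv(s1, s2)
    }
  })
  expect_lt(abs(mean(iccs) - sb^2 / (sb^2 + sw^2)),
            3 * stats::sd(iccs) / sqrt(nrep))
  expect_lt(abs(mean(wscvs) - sw / mu * 100),
            3 * stats::sd(wscvs) / sqrt(nrep))
  expect_error(wscv(c(-1, 1), c(1, -1)), "grand mean")
})
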