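test_that("model subset selection reproduces the protocol DWI counts", {
  expect_identical(nDwi(selectModelSubset(refCsScheme, "kurtosis")), 85L)
  expect_identical(nDwi(selectModelSubset(refCsScheme, "dt")), 28L)
  expect_identical(nDwi(selectModelSubset(refShellScheme, "dt")), 30L)
  expect_identical(nDwi(selectModelSubset(refShellScheme, "kurtosis")),
                   120L)
  expect_error(selectModelSubset(refCsScheme, "noddi"))
})

test_that("noise-free tensors are recovered exactly", {
  cfg <- singleFiberConfig(direction = c(1, 1, 0))
  fit <- fitDti(simulateVoxelSignal(cfg, dtSub), dtSub)
  expect_lt(max(abs(fit@tensor - phantomTensors(cfg)[[1]])), 1e-9)
  expect_equal(fit@s0, 1, tolerance = 1e-9)
  tr <- groundTruth(cfg)
  expect_equal(fit@fa, tr$fa, tolerance = 1e-9)
  expect_equal(fit@md, tr$md, tolerance = 1e-9)
  # isotropic: FA vanishes
  fi <- fitDti(simulateVoxelSignal(isotropicConfig(), dtSub), dtSub)
  expect_lt(fi@fa, 1e-6)
  # rank deficiency is reported
  coplanar <- schemeFromDirs(
    rbind(c(0, 0, 0),
          t(sapply(seq(0, pi * 0.9, length.out = 8), function(a)
            c(cos(a), sin(a), 0)))),
    c(0, rep(1000, 8)))
  expect_error(fitDti(simulateVoxelSignal(cfg, coplanar), coplanar),
               "rank-deficient")
})

test_that("DT fits on multi-b data shift MD as the curvature oracle predicts", {
  # two-compartment voxel: positive log-signal curvature
  mix <- phantomConfig(list(
    list(direction = c(1, 0, 0), fraction = 0.7,
         eigenvalues = c(1.7, 0.3, 0.3) * 1e-3),
    list(direction = c(1, 0, 0), fraction = 0.3,
         eigenvalues = c(3, 3, 3) * 1e-3)))
  multiFit <- fitDti(simulateVoxelSignal(mix, dtSub), dtSub)
  shellSub <- withB0(refShellScheme, selectModelSubset(refShellScheme, "dt"))
  shellFit <- fitDti(simulateVoxelSignal(mix, shellSub), shellSub)
  # the mixture's log signal is convex in b (positive kurtosis)
  bs <- seq(100, 1400, by = 100)
  dirs <- sphereTessellation(2L)$vertices
  lnE <- vapply(bs, function(b) {
    sch <- schemeFromDirs(dirs, rep(b, nrow(dirs)))
    mean(log(simulateVoxelSignal(mix, sch)))
  }, 0)
  curv <- stats::coef(stats::lm(lnE ~ poly(bs, 2, raw = TRUE)))[3]
  expect_gt(curv, 0)
  # direct least-squares oracle on the same inputs: scalar apparent
  # diffusivity per subset from a one-slope log-signal regression
  scalarD <- function(sub) {
    sig <- simulateVoxelSignal(mix, sub)
    -stats::coef(stats::lm(log(sig) ~ sub@entries$bval))[2]
  }
  expect_identical(unname(multiFit@md < shellFit@md),
                   unname(scalarD(dtSub) < scalarD(shellSub)))
  # both fits differ measurably on multi-b mixture data
  expect_gt(abs(multiFit@md - shellFit@md), 1e-6 * shellFit@md)
})

test_that("kurtosis vanishes in the Gaussian limit", {
  cfg <- singleFiberConfig(direction = c(0.3, -1, 0.4))
  fit <- fitDki(simulateVoxelSignal(cfg, kurtSub), kurtSub)
  dirs <- sphereTessellation(2L)$vertices
  expect_lt(max(abs(directionalKurtosis(fit, dirs))), 1e-6)
  expect_lt(abs(fit@mk), 1e-6)
  expect_lt(max(abs(fit@tensor - phantomTensors(cfg)[[1]])), 1e-9)
})

test_that("directional kurtosis matches the mixture cumulant oracle", {
  mix <- crossingFiberConfig(90)
  dirs <- sphereTessellation(1L)$vertices
  sch <- schemeFromDirs(
    rbind(matrix(0, 1, 3), dirs, dirs),
    c(0, rep(25, nrow(dirs)), rep(50, nrow(dirs))))
  fit <- fitDki(simulateVoxelSignal(mix, sch), sch,
                constraints = list(Kmin = -10, Kmax = 10))
  Ds <- phantomTensors(mix)
  oracle <- apply(dirs, 1L, function(u) {
    dg <- vapply(Ds, function(D) sum(u * (D %*% u)), 0)
    m <- mean(dg)                       # equal fractions
    3 * mean((dg - m)^2) / m^2
  })
  expect_lt(max(abs(directionalKurtosis(fit, dirs) - oracle)), 1e-3)
})

test_that("kurtosis constraints bound the fitted directional kurtosis", {
  # noisy crossing voxel: unconstrained fits overshoot; bounds must hold
  mix <- crossingFiberConfig(60, noiseSigma = 1 / 15, seed = 3L)
  dirs <- unique(as.matrix(kurtSub@entries[
    kurtSub@entries$bval > 0, c("dx", "dy", "dz")]))
  for (seed in 1:5) {
    sig <- simulateVoxelSignal(mix, kurtSub, noise = TRUE, seed = seed)
    fit <- fitDki(sig, kurtSub)
    k <- directionalKurtosis(fit, dirs)
    expect_true(all(k <= 3 + 1e-6))
    expect_true(all(k >= -1e-6))
  }
  # single b-value is rejected
  oneB <- schemeFromDirs(rbind(matrix(0, 1, 3),
                               sphereTessellation(1L)$vertices),
                         c(0, rep(1000, 42)))
  expect_error(fitDki(simulateVoxelSignal(mix, oneB), oneB),
               "unidentifiable")
})

test_that("noisy fits track the Rician-bias oracle at SNR 30", {
  sigma <- 1 / 30
  cfg <- singleFiberConfig(noiseSigma = sigma)
  clean <- simulateVoxelSignal(cfg, dtSub)
  nvox <- 200L
  fas <- mds <- numeric(nvox)
  withr::with_seed(11, {
    for (v in seq_len(nvox)) {
      n1 <- stats::rnorm(length(clean), 0, sigma)
      n2 <- stats::rnorm(length(clean), 0, sigma)
      f <- fitDti(sqrt((clean + n1)^2 + n2^2), dtSub)
      fas[v] <- f@fa; mds[v] <- f@md
    }
    # oracle: the same fit applied to the 10,000-realization average
    nrep <- 10000L
    avg <- numeric(length(clean))
    for (r in seq_len(nrep)) {
      n1 <- stats::rnorm(length(clean), 0, sigma)
      n2 <- stats::rnorm(length(clean), 0, sigma)
      avg <- avg + sqrt((clean + n1)^2 + n2^2)
    }
    avg <- avg / nrep
  })
  oracleFit <- fitDti(avg, dtSub)
  tr <- groundTruth(cfg)
  seMedian <- function(x) 1.2533 * stats::sd(x) / sqrt(length(x))
  expect_lt(abs((stats::median(fas) - tr$fa) - (oracleFit@fa - tr$fa)),
            3 * seMedian(fas))
  expect_lt(abs((stats::median(mds) - tr$md) - (oracleFit@md - tr$md)),
            3 * seMedian(mds))
})

test_that("the kurtosis model tempers multi-b FA bias relative to DT", {
  errK <- errD <- c()
  for (fiso in c(0.1, 0.15, 0.2, 0.25, 0.3)) {
    mix <- phantomConfig(list(
      list(direction = c(1, 0, 0), fraction = 1 - fiso,
           eigenvalues = c(1.7, 0.3, 0.3) * 1e-3),
      list(direction = c(0, 0, 1), fraction = fiso,
           eigenvalues = c(3, 3, 3) * 1e-3)))
    truFA <- groundTruth(mix)$fa
    fk <- fitDki(simulateVoxelSignal(mix, kurtSub), kurtSub)
    fd <- fitDti(simulateVoxelSignal(mix, dtSub), dtSub)
    errK <- c(errK, abs(fk@fa - truFA))
    errD <- c(errD, abs(fd@fa - truFA))
  }
  expect_lte(stats::median(errK), stats::median(errD))
})
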