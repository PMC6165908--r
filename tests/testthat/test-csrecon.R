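test_that("soft thresholding follows its closed form", {
  expect_equal(softThreshold(0, 1), 0)
  expect_equal(softThreshold(c(0.5, -0.9), 1), c(0, 0))
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(c(-3, 2), 1), c(-2, 1))
  expect_error(softThreshold(1, -0.1), ">= 0")
})

test_that("forward/adjoint pair satisfies the operator contracts", {
  set.seed(1)
  N <- 7L
  mask <- array(stats::runif(N^3) < 0.4, rep(N, 3L))
  x <- array(stats::rnorm(N^3), rep(N, 3L))
  v <- complex(real = stats::rnorm(sum(mask)),
               imaginary = stats::rnorm(sum(mask)))
  lhs <- sum(qspaceForward(x, mask) * Conj(v))
  rhs <- sum(x * Conj(qspaceAdjoint(v, mask)))
  expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-10)
  # unitarity with the full mask
  full <- array(TRUE, rep(N, 3L))
  xr <- Re(qspaceAdjoint(qspaceForward(x, full), full))
  expect_lt(max(abs(xr - x)), 1e-12)
  # delta at the q-origin transforms to a constant
  ctr <- N %/% 2L + 1L
  d <- array(0, rep(N, 3L)); d[ctr, ctr, ctr] <- 1
  Econst <- csdsi:::centeredDft(d)
  expect_lt(diff(range(Re(Econst))), 1e-12)
  expect_lt(max(abs(Im(Econst))), 1e-12)
  expect_error(qspaceForward(x, mask[1:3, 1:3, 1:3]), "shape")
})

test_that("fully sampled noise-free data is recovered exactly at lambda 0", {
  g <- buildGrid(3L, 6800)
  rows <- which(uniquePoints(g))
  sch <- csdsi:::schemeFromGridRows(g, rows, rep(TRUE, length(rows)),
                                    "full", NULL)
  sig <- simulateVoxelSignal(singleFiberConfig(), sch)
  prob <- csProblem(sig, sch, g, lambda = 0, maxIter = 50L, tol = 1e-14)
  rec <- istaReconstruct(prob)
  truth <- simulateVoxelSignal(singleFiberConfig(), rec$scheme)
  expect_lt(nmse(rec$signals, truth), 1e-10)
})

test_that("the mask bookkeeping matches the antipodal-mirror contract", {
  prob <- csProblem(simulateVoxelSignal(singleFiberConfig(), refCsScheme),
                    refCsScheme, refGrid)
  expect_identical(sum(prob@mask), 2L * 112L + 1L)
  ctr <- refGrid@radius + 1L
  lin <- array(seq_len(11L^3), rep(11L, 3L))[ctr, ctr, ctr]
  expect_equal(prob@y[which(which(prob@mask) == lin)], 1)
  sig <- simulateVoxelSignal(singleFiberConfig(), refCsScheme)
  sig[20] <- NA
  expect_error(csProblem(sig, refCsScheme, refGrid), "NaN")
})

test_that("ISTA matches an independent dense-matrix solver on a tiny grid", {
  g <- buildGrid(2L, 6800)
  rows <- which(uniquePoints(g) & rowSums(gridPoints(g)^2) > 0)
  allRows <- which(uniquePoints(g))
  meas <- withr::with_seed(7, sort(sample(rows, length(rows) %/% 2)))
  sch <- csdsi:::schemeFromGridRows(g, allRows, allRows %in% meas,
                                    "tiny", NULL)
  sig <- simulateVoxelSignal(singleFiberConfig(), sch)
  lam <- 5e-6
  prob <- csProblem(sig, sch, g, lambda = lam, maxIter = 20000L, tol = 0)
  # solver-scale solution via the package path
  rec <- suppressWarnings(istaReconstruct(prob))
  y <- prob@y; mask <- prob@mask
  pIsta <- Re(qspaceAdjoint(y, mask))
  lam0 <- max(abs(pIsta)) / 2
  for (lk in exp(seq(log(lam0), log(lam), length.out = 20)))
    for (i in 1:150)
      pIsta <- softThreshold(pIsta - Re(qspaceAdjoint(
        qspaceForward(pIsta, mask) - y, mask)), lk)
  for (i in 1:20000)
    pIsta <- softThreshold(pIsta - Re(qspaceAdjoint(
      qspaceForward(pIsta, mask) - y, mask)), lam)

  # independent oracle: explicit dense DFT matrix, 10x smaller step,
  # 10x the final iterations
  N <- 5L; n <- N^3
  Fm <- matrix(0 + 0i, n, n)
  for (j in seq_len(n)) {
    e <- array(0, rep(N, 3L)); e[j] <- 1
    Fm[, j] <- as.vector(csdsi:::centeredDft(e))
  }
  A <- Fm[as.vector(mask), ]
  AH <- Conj(t(A))
  step <- 0.1
  pd <- Re(AH %*% y)
  for (lk in exp(seq(log(max(abs(pd)) / 2), log(lam), length.out = 20)))
    for (i in 1:1500)
      pd <- softThreshold(Re(pd - step * (AH %*% (A %*% pd - y))),
                          step * lk)
  for (i in 1:100000)
    pd <- softThreshold(Re(pd - step * (AH %*% (A %*% pd - y))),
                        step * lam)
  relErr <- sqrt(sum((as.vector(pIsta) - as.vector(pd))^2) / sum(pd^2))
  expect_lt(relErr, 1e-4)

  # generic convex-programming cross-check: glmnet reaches the same
  # objective value (the minimizer itself is not unique at this lambda)
  objective <- function(pv) {
    r <- A %*% pv - y
    Re(0.5 * sum(Mod(r)^2) + lam * sum(abs(pv)))
  }
  Ar <- rbind(Re(A), Im(A)); yr <- c(Re(y), Im(y))
  fitg <- glmnet::glmnet(Ar, yr, lambda = lam / nrow(Ar),
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-16, maxit = 1e7)
  pg <- as.numeric(stats::coef(fitg))[-1]
  expect_equal(objective(as.vector(pIsta)), objective(pg),
               tolerance = 1e-6)
})

test_that("the ISTA objective never increases across iterations", {
  sig <- simulateVoxelSignal(crossingFiberConfig(60), refCsScheme)
  prob <- csProblem(sig, refCsScheme, refGrid, maxIter = 300L, tol = 0)
  rec <- suppressWarnings(istaReconstruct(prob, continuation = FALSE))
  expect_true(all(diff(rec$objective) <= 1e-12))
  expect_false(rec$converged)
  # with the warm start the default tolerance is met
  prob2 <- csProblem(sig, refCsScheme, refGrid)
  rec2 <- istaReconstruct(prob2)
  expect_true(rec2$converged)
  expect_true(all(diff(rec2$objective) <= 1e-12))
})

test_that("CS reconstruction beats the zero-filled baseline on phantoms", {
  cfg <- singleFiberConfig(direction = c(1, 2, 0.5))
  sig <- simulateVoxelSignal(cfg, refCsScheme)
  prob <- csProblem(sig, refCsScheme, refGrid)
  rec <- istaReconstruct(prob)
  zf <- zeroFilledReconstruct(prob)
  truth <- simulateVoxelSignal(cfg, rec$scheme)
  expect_lt(nmse(rec$signals, truth), nmse(zf$signals, truth))
  expect_lt(nmse(rec$signals, truth), 0.01)
  # the reconstructed propagator is a probability mass function
  p <- rec$propagator
  expect_true(all(p@values >= 0))
  expect_equal(sum(p@values), 1)
  # antipodal symmetry of the recovered propagator
  flip <- p@values[11:1, 11:1, 11:1]
  expect_lt(max(abs(p@values - flip)), 1e-6)
})
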