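#' Generate a staggered multi-shell sampling scheme
#'
#' Places the requested number of directions on each b-value shell by
#' minimizing a generalized antipodally symmetric electrostatic-repulsion
#' energy: every pair of direction lines i, j contributes
#' `w_ij * (1/|u_i - u_j| + 1/|u_i + u_j|)`, with weight 1 within a shell and
#' `interShellWeight` (default 0.5) across shells. The cross-shell term
#' staggers the shells jointly (Caruyer-style incremental multi-shell
#' design), so directions on different shells avoid each other as well.
#' Minimization is projected gradient descent with backtracking from a
#' seeded random start; the energy is non-increasing across iterations by
#' construction.
#'
#' @param shells Two-column matrix, data frame or list of `c(b, n)` pairs:
#'   shell b-value (s/mm^2, > 0) and direction count (>= 1).
#' @param seed Integer seed (deterministic output given the seed).
#' @param meta Protocol metadata; its `nB0` b = 0 entries are prepended
#'   (default [multishellMeta()], 14 b = 0 scans).
#' @param maxIter Gradient-descent iteration budget.
#' @param interShellWeight Weight of the cross-shell repulsion term.
#' @return A [SamplingScheme-class] with all entries `measured = TRUE`. The
#'   optimizer's energy trace is stored in `attr(scheme, "energyTrace")`.
#' @examples
#' s <- generateMultishellScheme(rbind(c(1000, 30), c(2000, 40), c(3000, 50)),
#'                               seed = 1L)
#' nDwi(s)   # 120
#' @export
generateMultishellScheme <- function(shells, seed = 1L,
                                     meta = multishellMeta(),
                                     maxIter = 400L,
                                     interShellWeight = 0.5) {
  if (is.list(shells) && !is.data.frame(shells))
    shells <- do.call(rbind, shells)
  shells <- as.matrix(shells)
  if (ncol(shells) != 2L) stop("shells must be (b, n) pairs")
  bs <- shells[, 1]; ns <- as.integer(shells[, 2])
  if (any(bs <= 0)) stop("shell b-values must be positive")
  if (any(ns < 1L)) stop("shell direction counts must be >= 1")

  shellOf <- rep(seq_along(ns), ns)
  n <- length(shellOf)
  w <- ifelse(outer(shellOf, shellOf, "=="), 1, interShellWeight)
  diag(w) <- 0

  energyOf <- function(u) {
    dif <- as.matrix(stats::dist(u))
    sm <- as.matrix(stats::dist(rbind(u, -u)))[seq_len(n), n + seq_len(n)]
    diag(dif) <- Inf
    diag(sm) <- Inf   # self antipode distance 2: constant, drop for stability
    sum(w * (1 / dif + 1 / sm)) / 2
  }
  gradOf <- function(u) {
    g <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      dif <- sweep(-u, 2L, -u[i, ])          # u_i - u_j rows
      sm <- sweep(u, 2L, u[i, ], "+")        # u_i + u_j rows
      dd <- sqrt(rowSums(dif^2)); ds <- sqrt(rowSums(sm^2))
      dd[i] <- Inf; ds[i] <- Inf
      g[i, ] <- colSums(w[i, ] * (-dif / dd^3 - sm / ds^3))
    }
    g
  }

  u <- withSeed(seed, {
    m <- matrix(stats::rnorm(3L * n), n, 3L)
    normalizeRows(m)
  })
  e <- energyOf(u)
  trace_ <- e
  step <- 0.1 / n
  for (it in seq_len(maxIter)) {
    g <- gradOf(u)
    g <- g - u * rowSums(g * u)              # tangent projection
    accepted <- FALSE
    for (bt in 1:30) {
      cand <- normalizeRows(u - step * g)
      ec <- energyOf(cand)
      if (ec < e) { u <- cand; e <- ec; accepted <- TRUE; break }
      step <- step / 2
    }
    trace_ <- c(trace_, e)
    if (!accepted) break
    step <- step * 1.5
  }

  entries <- data.frame(dx = u[, 1], dy = u[, 2], dz = u[, 3],
                        bval = bs[shellOf],
                        qx = NA_integer_, qy = NA_integer_,
                        qz = NA_integer_, measured = TRUE)
  sch <- new("SamplingScheme", protocolId = "multishell",
             entries = entries, meta = meta)
  sch <- prependB0(sch, if (is.null(meta)) 0L else meta@nB0)
  attr(sch, "energyTrace") <- trace_
  sch
}
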