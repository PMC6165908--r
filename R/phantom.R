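#' Construct a multi-tensor phantom configuration
#'
#' @param compartments List of compartments, each a list with `direction`
#'   (3-vector, normalized internally), `fraction` and `eigenvalues`
#'   (length-3, mm^2/s: lambda_parallel, lambda_perp1, lambda_perp2).
#' @param S0 Non-diffusion-weighted signal level (default 1).
#' @param noiseSigma Rician noise scale at S0 (so SNR = S0/noiseSigma);
#'   default 0 (noise-free).
#' @param seed Integer seed used for noise realizations.
#' @return A [PhantomConfig-class].
#' @examples
#' # 90-degree crossing of two equal fibers
#' cfg <- phantomConfig(list(
#'   list(direction = c(1, 0, 0), fraction = 0.5,
#'        eigenvalues = c(1.7, 0.3, 0.3) * 1e-3),
#'   list(direction = c(0, 1, 0), fraction = 0.5,
#'        eigenvalues = c(1.7, 0.3, 0.3) * 1e-3)))
#' @export
phantomConfig <- function(compartments, S0 = 1, noiseSigma = 0, seed = 1L) {
  compartments <- lapply(compartments, function(cmp) {
    cmp$direction <- cmp$direction / sqrt(sum(cmp$direction^2))
    cmp$eigenvalues <- as.numeric(cmp$eigenvalues)
    cmp
  })
  new("PhantomConfig", compartments = compartments, S0 = as.numeric(S0),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

# Standard single-fiber / crossing / CSF-like configurations used as
# defaults: white-matter eigenvalues (1.7, 0.3, 0.3)e-3 mm^2/s, isotropic
# 3.0e-3 mm^2/s.

#' Stock phantom configurations
#'
#' `singleFiberConfig()` is one fiber along `direction`;
#' `crossingFiberConfig()` is two equal-fraction fibers separated by
#' `angleDeg` in the x-y plane; `isotropicConfig()` is CSF-like free
#' diffusion.
#'
#' @param direction Fiber direction for the single-fiber phantom.
#' @param angleDeg Crossing angle in degrees.
#' @param eigenvalues Per-fiber eigenvalues, mm^2/s.
#' @param d Isotropic diffusivity, mm^2/s.
#' @param ... Passed on to [phantomConfig()] (`S0`, `noiseSigma`, `seed`).
#' @return A [PhantomConfig-class].
#' @export
singleFiberConfig <- function(direction = c(1, 0, 0),
                              eigenvalues = c(1.7, 0.3, 0.3) * 1e-3, ...) {
  phantomConfig(list(list(direction = direction, fraction = 1,
                          eigenvalues = eigenvalues)), ...)
}

#' @rdname singleFiberConfig
#' @export
crossingFiberConfig <- function(angleDeg = 90,
                                eigenvalues = c(1.7, 0.3, 0.3) * 1e-3, ...) {
  a <- angleDeg * pi / 180
  phantomConfig(list(
    list(direction = c(1, 0, 0), fraction = 0.5, eigenvalues = eigenvalues),
    list(direction = c(cos(a), sin(a), 0), fraction = 0.5,
         eigenvalues = eigenvalues)), ...)
}

#' @rdname singleFiberConfig
#' @export
isotropicConfig <- function(d = 3.0e-3, ...) {
  phantomConfig(list(list(direction = c(1, 0, 0), fraction = 1,
                          eigenvalues = c(d, d, d))), ...)
}

# 3x3 diffusion tensor of a compartment (axis + eigenvalues).
compartmentTensor <- function(cmp) {
  e1 <- cmp$direction
  # any orthonormal completion
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  ev <- cmp$eigenvalues
  ev[1] * outer(e1, e1) + ev[2] * outer(e2, e2) + ev[3] * outer(e3, e3)
}

#' Compartment tensors of a phantom
#'
#' @param config A [PhantomConfig-class].
#' @return List of symmetric 3 x 3 tensors, one per compartment.
#' @export
phantomTensors <- function(config) lapply(config@compartments,
                                          compartmentTensor)

#' Closed-form ground-truth scalar maps of a phantom
#'
#' For the Gaussian part of the mixture (the fraction-weighted average
#' tensor, i.e. the b -> 0 effective tensor) returns FA, MD, AD and RD by
#' the standard eigenvalue formulas, together with the fiber directions and
#' fractions.
#'
#' @param config A [PhantomConfig-class].
#' @return List with `fa`, `md`, `ad`, `rd`, `tensor`, `directions`
#'   (k x 3 matrix), `fractions`.
#' @export
groundTruth <- function(config) {
  Ds <- phantomTensors(config)
  fr <- vapply(config@compartments, function(x) x$fraction, 0)
  Dbar <- Reduce(`+`, Map(`*`, Ds, fr))
  ev <- sort(eigen(Dbar, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(tensorScalars(ev),
    list(tensor = Dbar,
         directions = t(vapply(config@compartments,
                               function(x) x$direction, numeric(3))),
         fractions = fr))
}

# FA/MD/AD/RD from eigenvalues (descending).
tensorScalars <- function(ev) {
  md <- mean(ev)
  fa <- if (sum(ev^2) == 0) 0 else
    sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
  list(fa = fa, md = md, ad = ev[1], rd = mean(ev[2:3]))
}

#' Simulate the diffusion signal of one phantom voxel
#'
#' Noise-free attenuation is the Gaussian mixture
#' `E(g, b) = sum_i f_i exp(-b g' D_i g)` and the signal is `S0 * E`. With
#' `noise = TRUE`, magnitude (Rician) noise is applied:
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`, seeded from
#' `config@seed` unless `seed` is given.
#'
#' @param config A [PhantomConfig-class].
#' @param scheme A [SamplingScheme-class]; one signal value is produced per
#'   entry (b = 0 entries give S0 noise-free).
#' @param noise Add Rician noise?
#' @param seed Optional seed overriding `config@seed`.
#' @return Numeric signal vector of length `nrow(scheme@entries)`.
#' @export
simulateVoxelSignal <- function(config, scheme, noise = FALSE, seed = NULL) {
  stopifnot(is(config, "PhantomConfig"), is(scheme, "SamplingScheme"))
  g <- directions(scheme)
  b <- bValues(scheme)
  s <- config@S0 * mixtureAttenuation(config, g, b)
  if (noise && config@noiseSigma > 0) {
    s <- withSeed(if (is.null(seed)) config@seed else seed, {
      n1 <- stats::rnorm(length(s), 0, config@noiseSigma)
      n2 <- stats::rnorm(length(s), 0, config@noiseSigma)
      sqrt((s + n1)^2 + n2^2)
    })
  }
  s
}

# Attenuation at arbitrary (direction, b) pairs; g rows need not be unit
# for b = 0 rows (ignored).
mixtureAttenuation <- function(config, g, b) {
  e <- numeric(length(b))
  for (cmp in config@compartments) {
    D <- compartmentTensor(cmp)
    quad <- rowSums((g %*% D) * g)
    e <- e + cmp$fraction * exp(-b * quad)
  }
  e[b == 0] <- 1
  e
}

#' Evaluate phantom attenuation on a full q-space cube
#'
#' Evaluates the noise-free mixture attenuation at every point of the full
#' cubic lattice enclosing a [CartesianQGrid-class] (extent
#' `(2 radius + 1)^3`), with the grid's quadratic b-value mapping continued
#' beyond the truncation sphere. This is the natural input for
#' [propagatorFromSignals()], since the discrete Fourier inversion operates
#' on the whole cube.
#'
#' @param config A [PhantomConfig-class].
#' @param grid A [CartesianQGrid-class].
#' @return 3D array (centred order) of attenuation values.
#' @export
simulateCubeSignal <- function(config, grid) {
  r <- grid@radius
  ax <- seq.int(-r, r)
  pts <- as.matrix(expand.grid(qx = ax, qy = ax, qz = ax,
                               KEEP.OUT.ATTRS = FALSE))
  n2 <- rowSums(pts^2)
  b <- if (r == 0L) rep(0, nrow(pts)) else grid@bMax * n2 / r^2
  g <- normalizeRows(pts)
  e <- mixtureAttenuation(config, g, b)
  array(e, dim = rep(2L * r + 1L, 3L))
}

#' Build a phantom volume with ground truth
#'
#' Lays out non-overlapping labelled regions, each holding one
#' [PhantomConfig-class], over a 3D voxel grid and simulates the signal of
#' every voxel for the given scheme (channel order = scheme order). The
#' noise-free volume is deterministic; noise realizations are seeded per
#' voxel from `seed`.
#'
#' @param layout List of regions: each a list with `label`, `voxels`
#'   (n x 3 integer matrix of voxel indices) and `config`.
#' @param dim Volume dimensions (3-vector); defaults to the bounding box of
#'   the layout.
#' @param scheme A [SamplingScheme-class].
#' @param noise Add Rician noise per voxel?
#' @param seed Integer seed for the noise stream.
#' @return List with `volume` (4D array), `labels` (3D integer array, 0
#'   outside all regions), and `truth` (per-region [groundTruth()] lists,
#'   named by label).
#' @export
makePhantomVolume <- function(layout, scheme, dim = NULL, noise = FALSE,
                              seed = 1L) {
  allVox <- do.call(rbind, lapply(layout, function(r) r$voxels))
  if (anyDuplicated(allVox))
    stop("overlapping regions: layout voxels must partition the mask")
  if (is.null(dim)) dim <- apply(allVox, 2L, max)
  nv <- nrow(scheme@entries)
  vol <- array(0, c(dim, nv))
  labels <- array(0L, dim)
  truth <- list()
  vseed <- seed
  for (ri in seq_along(layout)) {
    reg <- layout[[ri]]
    truth[[reg$label]] <- groundTruth(reg$config)
    base <- simulateVoxelSignal(reg$config, scheme, noise = FALSE)
    for (vi in seq_len(nrow(reg$voxels))) {
      v <- reg$voxels[vi, ]
      s <- base
      if (noise && reg$config@noiseSigma > 0) {
        vseed <- vseed + 1L
        s <- withSeed(vseed, {
          n1 <- stats::rnorm(nv, 0, reg$config@noiseSigma)
          n2 <- stats::rnorm(nv, 0, reg$config@noiseSigma)
          sqrt((base + n1)^2 + n2^2)
        })
      }
      vol[v[1], v[2], v[3], ] <- s
      labels[v[1], v[2], v[3]] <- ri
    }
  }
  list(volume = vol, labels = labels, truth = truth)
}

#' Simulate paired scan/rescan datasets for test-retest analysis
#'
#' Emulates a test-retest substudy: each simulated subject receives a
#' subject-level offset of the phantom's eigenvalue scale (multiplicative,
#' `1 + delta` with `delta ~ N(0, betweenSd^2)`) and two independent Rician
#' noise realizations of the same voxel signal - a scan and a same-day
#' rescan. The generating variance components are returned so recovered
#' ICC/wsCV can be checked against their closed forms.
#'
#' @param config Base [PhantomConfig-class] (its `noiseSigma` is the
#'   within-subject noise).
#' @param scheme A [SamplingScheme-class].
#' @param nSubjects Number of subjects (>= 2; the reference test-retest
#'   subgroup size is 5).
#' @param betweenSd Standard deviation of the between-subject eigenvalue
#'   scale offset.
#' @param seed Integer seed.
#' @return List with `scan` and `rescan` (matrices, subjects x volumes),
#'   `subjectScale` (the drawn per-subject scales) and `components`
#'   (list: `betweenSd`, `noiseSigma`).
#' @export
trtReplicates <- function(config, scheme, nSubjects = 5L, betweenSd = 0,
                          seed = 1L) {
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  nv <- nrow(scheme@entries)
  withSeed(seed, {
    scales <- 1 + stats::rnorm(nSubjects, 0, betweenSd)
    scan <- rescan <- matrix(0, nSubjects, nv)
    for (s in seq_len(nSubjects)) {
      cfg <- config
      cfg@compartments <- lapply(cfg@compartments, function(cmp) {
        cmp$eigenvalues <- cmp$eigenvalues * scales[s]
        cmp
      })
      base <- simulateVoxelSignal(cfg, scheme, noise = FALSE)
      for (rep_ in 1:2) {
        sig <- base
        if (config@noiseSigma > 0) {
          n1 <- stats::rnorm(nv, 0, config@noiseSigma)
          n2 <- stats::rnorm(nv, 0, config@noiseSigma)
          sig <- sqrt((base + n1)^2 + n2^2)
        }
        if (rep_ == 1L) scan[s, ] <- sig else rescan[s, ] <- sig
      }
    }
    list(scan = scan, rescan = rescan, subjectScale = scales,
         components = list(betweenSd = betweenSd,
                           noiseSigma = config@noiseSigma))
  })
}
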