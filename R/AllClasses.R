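#' @import methods
NULL

setClassUnion("ProtocolMetaOrNULL", "NULL")

#' Acquisition protocol metadata
#'
#' Sequence timing parameters of a diffusion MRI protocol. The effective
#' diffusion time tau = Delta - delta/3 (narrow-pulse corrected) is derived
#' from the gradient pulse separation `Delta` and duration `delta`, and sets
#' the q-to-displacement scaling used by propagator metrics.
#'
#' @slot te Echo time, ms.
#' @slot tr Repetition time, ms.
#' @slot Delta Gradient pulse separation, ms.
#' @slot delta Gradient pulse duration, ms.
#' @slot nB0 Number of interleaved b = 0 volumes in the protocol.
#'
#' @seealso [protocolMeta()], [diffusionTime()]
#' @export
setClass("ProtocolMeta",
  representation(te = "numeric", tr = "numeric", Delta = "numeric",
                 delta = "numeric", nB0 = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@te, object@tr, object@Delta, object@delta) <= 0))
      msg <- c(msg, "TE, TR, Delta and delta must all be positive")
    if (length(object@delta) && length(object@Delta) &&
        object@delta >= object@Delta)
      msg <- c(msg, "gradient pulse duration delta must be < separation Delta")
    if (object@nB0 < 0L) msg <- c(msg, "nB0 must be non-negative")
    if (length(msg)) msg else TRUE
  })
setIs("ProtocolMeta", "ProtocolMetaOrNULL")

#' Cartesian q-space grid
#'
#' The truncated-sphere lattice of q-space sample positions used by diffusion
#' spectrum imaging: all integer triples (qx, qy, qz) with
#' qx^2 + qy^2 + qz^2 <= radius^2, in lexicographic (qz, qy, qx) order.
#' The b-value at a lattice point scales with its squared norm,
#' b = bMax * |q|^2 / radius^2, so the maximum b-value sits on the sphere
#' boundary. For the standard radius-5 grid (11 x 11 x 11 extent) this gives
#' 515 points, of which 258 are antipodally unique and 257 are unique and
#' diffusion-weighted.
#'
#' @slot radius Integer lattice radius (5 for the 11^3 grid).
#' @slot bMax b-value at |q| = radius, s/mm^2.
#' @slot points Integer matrix (n x 3) of lattice coordinates.
#'
#' @seealso [buildGrid()], [bValues()], [uniquePoints()]
#' @export
setClass("CartesianQGrid",
  representation(radius = "integer", bMax = "numeric", points = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@radius < 0L) msg <- c(msg, "radius must be non-negative")
    if (object@bMax <= 0) msg <- c(msg, "bMax must be positive")
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
    if (any(rowSums(object@points^2) > object@radius^2))
      msg <- c(msg, "all points must lie within the truncation sphere")
    if (length(msg)) msg else TRUE
  })

#' Gradient sampling scheme
#'
#' An ordered gradient table: one row per volume with a unit diffusion
#' direction (zero vector iff b = 0), a b-value, the originating q-space
#' lattice point where applicable, and a flag marking whether the volume is
#' actually measured (compressed-sensing schemes mark the non-acquired grid
#' samples `measured = FALSE`; they are recovered by reconstruction).
#'
#' @slot protocolId Label, e.g. "cs-dsi" or "3-shell".
#' @slot entries Data frame with columns `dx, dy, dz` (unit direction),
#'   `bval` (s/mm^2), `qx, qy, qz` (lattice triple or NA), `measured`.
#' @slot meta A [ProtocolMeta-class] or `NULL`.
#'
#' @seealso [generateCsScheme()], [generateMultishellScheme()],
#'   [readFslGradients()]
#' @export
setClass("SamplingScheme",
  representation(protocolId = "character", entries = "data.frame",
                 meta = "ProtocolMetaOrNULL"),
  validity = function(object) {
    e <- object@entries
    need <- c("dx", "dy", "dz", "bval", "qx", "qy", "qz", "measured")
    if (!all(need %in% names(e)))
      return(paste("entries must have columns:", paste(need, collapse = ", ")))
    nrm <- sqrt(e$dx^2 + e$dy^2 + e$dz^2)
    dw <- e$bval > 0
    msg <- character()
    if (any(abs(nrm[dw] - 1) > 1e-6))
      msg <- c(msg, "diffusion-weighted directions must have unit norm (1e-6)")
    if (any(nrm[!dw] > 1e-12))
      msg <- c(msg, "b = 0 entries must have zero direction vectors")
    if (any(e$bval < 0)) msg <- c(msg, "b-values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Reconstructed diffusion propagator
#'
#' The 3D displacement-space probability array recovered from q-space data by
#' (regularized) Fourier inversion. Values are stored in centred order (the
#' zero-displacement bin at the array centre) and sum to one: each element is
#' the probability mass of one displacement-space voxel. The physical voxel
#' pitch `spacingMm` derives from the q-space pitch via dr = 1/(N * dq), where
#' dq = sqrt(bMax / tau) / (2 * pi * radius) under the q = gamma * G * delta /
#' (2 * pi) convention; metrics are reported in grid units and in mm.
#'
#' @slot values Real 3D array (N^3), centred, non-negative, summing to 1.
#' @slot spacingMm Displacement voxel pitch in mm (NA when no timing
#'   metadata is available).
#' @slot gridRadius Radius of the originating q-space grid.
#' @slot info List of solver diagnostics (objective trace, iterations,
#'   converged flag) when produced by [istaReconstruct()].
#'
#' @seealso [propagatorFromSignals()], [istaReconstruct()], [msd()], [rtop()]
#' @export
setClass("Propagator",
  representation(values = "array", spacingMm = "numeric",
                 gridRadius = "integer", info = "list"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || length(unique(d)) != 1L)
      return("values must be a cubic 3D array")
    if (d[1] %% 2L != 1L) return("array extent must be odd (centred grid)")
    TRUE
  })

#' Diffusion orientation distribution function
#'
#' A spherical function obtained by radially integrating the diffusion
#' propagator (weight r^2, classical DSI convention), sampled on an
#' antipodally symmetric sphere tessellation (subdivided icosahedron).
#'
#' @slot directions Unit vectors (m x 3), antipodally paired.
#' @slot values Non-negative amplitudes, one per direction.
#' @slot faces Integer triangle matrix (f x 3) defining the tessellation
#'   neighbourhood graph used by peak extraction.
#'
#' @seealso [dodf()], [extractPeaks()]
#' @export
setClass("DODF",
  representation(directions = "matrix", values = "numeric", faces = "matrix"),
  validity = function(object) {
    if (nrow(object@directions) != length(object@values))
      return("directions and values must agree in length")
    if (any(abs(sqrt(rowSums(object@directions^2)) - 1) > 1e-8))
      return("directions must be unit vectors")
    TRUE
  })

#' Extracted ODF peak set
#'
#' Local maxima of a spherical function, ordered by amplitude, with the
#' relative fraction of each peak (its amplitude as a share of the summed
#' peak amplitudes) standing in for a per-fiber partial volume fraction.
#'
#' @slot peaks Data frame with columns `dx, dy, dz, amplitude, fraction`.
#'
#' @seealso [extractPeaks()], [fiberCount()], [angularPeakDifference()]
#' @export
setClass("PeakSet",
  representation(peaks = "data.frame"),
  validity = function(object) {
    need <- c("dx", "dy", "dz", "amplitude", "fraction")
    if (!all(need %in% names(object@peaks)))
      return(paste("peaks must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@peaks) && is.unsorted(rev(object@peaks$amplitude)))
      return("peaks must be ordered by descending amplitude")
    TRUE
  })

#' Fitted diffusion tensor
#'
#' Result of a weighted linear least-squares diffusion tensor fit, with the
#' standard scalar maps derived from the tensor eigenvalues.
#'
#' @slot tensor Symmetric 3 x 3 diffusion tensor, mm^2/s.
#' @slot s0 Estimated non-diffusion-weighted signal.
#' @slot fa,md,ad,rd Fractional anisotropy (dimensionless) and mean, axial,
#'   radial diffusivity (mm^2/s).
#' @slot evals Tensor eigenvalues, descending.
#' @slot evecs Eigenvector matrix (columns).
#' @slot nmse Residual normalized mean squared error of the fit.
#' @slot clamped TRUE if negative eigenvalues were clamped for the scalar
#'   maps.
#'
#' @seealso [fitDti()]
#' @export
setClass("TensorFit",
  representation(tensor = "matrix", s0 = "numeric", fa = "numeric",
                 md = "numeric", ad = "numeric", rd = "numeric",
                 evals = "numeric", evecs = "matrix", nmse = "numeric",
                 clamped = "logical"),
  validity = function(object) {
    if (any(dim(object@tensor) != c(3L, 3L))) return("tensor must be 3 x 3")
    if (max(abs(object@tensor - t(object@tensor))) > 1e-12)
      return("tensor must be symmetric")
    if (object@fa < -1e-9 || object@fa > 1 + 1e-9)
      return("FA must lie in [0, 1]")
    TRUE
  })

#' Fitted diffusion kurtosis model
#'
#' Result of the constrained weighted least-squares diffusion kurtosis fit:
#' the diffusion tensor D, the fully symmetric fourth-order kurtosis tensor W
#' (15 unique elements), tensor-derived scalars, and the kurtosis scalars MK,
#' AK and RK (mean over a uniform direction set, and along/perpendicular to
#' the principal eigenvector).
#'
#' @slot tensor Symmetric 3 x 3 diffusion tensor, mm^2/s.
#' @slot wTensor Numeric vector of the 15 unique kurtosis tensor elements in
#'   the order given by [dkiTermOrder()].
#' @slot s0 Estimated b = 0 signal.
#' @slot fa,md,ad,rd Tensor-derived scalars (from the kurtosis fit's D).
#' @slot mk,ak,rk Mean, axial and radial kurtosis.
#' @slot evals,evecs Tensor eigendecomposition.
#' @slot nmse Residual normalized mean squared error.
#' @slot constrained TRUE if the inequality-constrained refit was engaged.
#'
#' @seealso [fitDki()], [directionalKurtosis()]
#' @export
setClass("KurtosisFit",
  representation(tensor = "matrix", wTensor = "numeric", s0 = "numeric",
                 fa = "numeric", md = "numeric", ad = "numeric",
                 rd = "numeric", mk = "numeric", ak = "numeric",
                 rk = "numeric", evals = "numeric", evecs = "matrix",
                 nmse = "numeric", constrained = "logical"),
  validity = function(object) {
    if (length(object@wTensor) != 15L)
      return("wTensor must hold the 15 unique kurtosis elements")
    if (max(abs(object@tensor - t(object@tensor))) > 1e-12)
      return("tensor must be symmetric")
    TRUE
  })

#' Shell assignment of Cartesian-grid b-values
#'
#' The post hoc mapping of grid b-values onto a small set of nominal shells,
#' as required by shell-based preprocessing tools. The assignment is nominal
#' only: downstream computation keeps the original b-values.
#'
#' @slot centers Shell centre b-values, s/mm^2.
#' @slot table Data frame with columns `original`, `assigned`, `shift`
#'   (one row per volume).
#' @slot maxAbsShift Largest absolute nominal shift over all volumes.
#'
#' @seealso [assignShells()]
#' @export
setClass("ShellAssignment",
  representation(centers = "numeric", table = "data.frame",
                 maxAbsShift = "numeric"),
  validity = function(object) {
    if (!all(c("original", "assigned", "shift") %in% names(object@table)))
      return("table must have columns original, assigned, shift")
    if (nrow(object@table) &&
        !all(object@table$assigned %in% c(object@centers, 0)))
      return("every assigned b-value must be a shell centre (or 0)")
    if (nrow(object@table) &&
        abs(object@maxAbsShift - max(abs(object@table$shift))) > 1e-9)
      return("maxAbsShift must equal the maximum absolute shift")
    TRUE
  })

#' Multi-tensor phantom configuration
#'
#' Specification of a synthetic voxel as a mixture of Gaussian diffusion
#' compartments: per compartment a unit fiber direction, a signal fraction
#' and axially symmetric-or-not eigenvalues (lambda_parallel,
#' lambda_perp1, lambda_perp2). Signals follow
#' E(g, b) = sum_i f_i * exp(-b * g' D_i g); Rician noise of scale
#' `noiseSigma` (defined at S0, so SNR = S0/noiseSigma) is added on demand.
#'
#' @slot compartments List of lists with elements `direction` (unit
#'   3-vector), `fraction`, `eigenvalues` (length-3, mm^2/s, descending).
#' @slot S0 Non-diffusion-weighted signal level.
#' @slot noiseSigma Rician noise scale in signal units.
#' @slot seed Integer seed for noise realizations.
#'
#' @seealso [phantomConfig()], [simulateVoxelSignal()]
#' @export
setClass("PhantomConfig",
  representation(compartments = "list", S0 = "numeric",
                 noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    fr <- vapply(object@compartments, function(x) x$fraction, 0)
    msg <- character()
    if (abs(sum(fr) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1")
    for (cmp in object@compartments) {
      ev <- cmp$eigenvalues
      if (any(ev <= 0)) msg <- c(msg, "eigenvalues must be positive")
      if (ev[1] < max(ev[-1]) - 1e-15)
        msg <- c(msg, "lambda_parallel must be >= perpendicular eigenvalues")
      if (abs(sum(cmp$direction^2) - 1) > 1e-9)
        msg <- c(msg, "compartment directions must be unit vectors")
    }
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (object@S0 <= 0) msg <- c(msg, "S0 must be positive")
    if (length(msg)) unique(msg) else TRUE
  })

#' Diffusion-weighted dataset
#'
#' A 4D volume array bound to its sampling scheme, an optional brain mask and
#' a provenance record, with the invariant that the number of volumes equals
#' the number of scheme entries.
#'
#' @slot volumes 4D numeric array (x, y, z, volume).
#' @slot scheme The [SamplingScheme-class] describing the 4th dimension.
#' @slot mask Optional 3D logical array (zero-length array if absent).
#' @slot provenance List carried through reads/writes (seeds, parameters,
#'   source paths).
#'
#' @seealso [dataset()], [readVolume()], [writeVolume()]
#' @export
setClass("Dataset",
  representation(volumes = "array", scheme = "SamplingScheme",
                 mask = "array", provenance = "list"),
  validity = function(object) {
    if (length(dim(object@volumes)) != 4L)
      return("volumes must be a 4D array")
    if (dim(object@volumes)[4] != nrow(object@scheme@entries))
      return("4th-dimension length must equal the scheme length")
    if (length(object@mask) &&
        !all(dim(object@mask) == dim(object@volumes)[1:3]))
      return("mask dimensions must match the volume grid")
    TRUE
  })
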