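#' b-values of a grid or scheme
#'
#' @param x A [CartesianQGrid-class] or [SamplingScheme-class].
#' @return Numeric vector of b-values (s/mm^2), one per grid point or scheme
#'   entry.
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' Diffusion directions
#'
#' @param x A [SamplingScheme-class] or [PeakSet-class].
#' @return Matrix (n x 3) of direction vectors (zero rows for b = 0 entries).
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' Number of diffusion-weighted volumes
#'
#' @param x A [SamplingScheme-class].
#' @param measuredOnly Count only entries flagged as measured?
#' @return Integer count of b > 0 entries.
#' @export
setGeneric("nDwi", function(x, measuredOnly = FALSE) standardGeneric("nDwi"))

#' Restrict to a b-value range
#'
#' Returns the antipodally unique, diffusion-weighted subset of a grid or
#' scheme whose b-values lie in `[bLo, bHi]` (inclusive), preserving order.
#' This implements the per-model sample selection used when fitting tensor or
#' kurtosis models to protocols spanning many b-values.
#'
#' @param x A [CartesianQGrid-class] or [SamplingScheme-class].
#' @param bLo,bHi Inclusive b-value bounds, s/mm^2 (`bLo <= bHi`).
#' @return A [SamplingScheme-class] subset. An empty selection is legal and
#'   emits a warning.
#' @examples
#' g <- buildGrid(5L, 6800)
#' nDwi(selectByBvalue(g, 1, 3000))   # 85 on the radius-5 grid
#' @export
setGeneric("selectByBvalue",
           function(x, bLo, bHi) standardGeneric("selectByBvalue"))

#' Mean squared displacement of a propagator
#'
#' MSD = sum_r P(r) * |r|^2 over the displacement grid. For free Gaussian
#' diffusion with diffusivity d and effective diffusion time tau, MSD is
#' 6 * d * tau (Einstein relation), which the discrete estimator approaches
#' at adequate grid resolution.
#'
#' @param p A [Propagator-class] (normalized internally, with a warning, if
#'   its mass does not sum to one).
#' @return Named list with `grid` (grid units^2) and `mm2` (mm^2, NA without
#'   timing metadata).
#' @export
setGeneric("msd", function(p) standardGeneric("msd"))

#' Return-to-origin probability of a propagator
#'
#' RTOP = P(0) / (displacement voxel volume): the probability density of zero
#' net displacement. For free Gaussian diffusion RTOP is
#' (4 * pi * d * tau)^(-3/2). The cube root, which scales like an inverse
#' length, is returned alongside.
#'
#' @param p A [Propagator-class].
#' @return Named list with `grid`, `gridCbrt` (grid units) and `mm`,
#'   `mmCbrt` (physical units, NA without timing metadata).
#' @export
setGeneric("rtop", function(p) standardGeneric("rtop"))

#' Diffusion ODF by radial projection
#'
#' Evaluates the classical DSI diffusion orientation distribution function
#' Phi(u) = integral_0^rmax P(r * u) r^2 dr by trilinear interpolation of the
#' propagator on equidistant radial samples (step 0.5 grid units), with the
#' antipodal average enforced.
#'
#' @param p A [Propagator-class].
#' @param directions Optional matrix of unit vectors; defaults to a
#'   subdivided-icosahedron tessellation with `nSubdiv` subdivisions.
#' @param rMax Radial integration limit in grid units (default: the grid
#'   radius; clipped to the array half-extent with a warning).
#' @param nSubdiv Icosahedron subdivision level used when `directions` is
#'   missing (3 gives 642 vertices).
#' @return A [DODF-class].
#' @export
setGeneric("dodf", function(p, directions = NULL, rMax = NULL, nSubdiv = 3L)
  standardGeneric("dodf"))

#' Extract peaks from a spherical function
#'
#' Finds local maxima over the tessellation neighbourhood graph, accepts them
#' greedily by descending amplitude subject to a minimum pairwise separation,
#' and discards peaks whose relative fraction (amplitude share of the
#' accepted peaks) does not exceed `relThreshold` - the operational analogue
#' of the "partial volume fraction > 0.1" rule used to count reliably
#' detected fibers.
#'
#' @param odf A [DODF-class].
#' @param relThreshold Relative-fraction threshold in `[0, 1]` (default 0.1).
#' @param minSep Minimum inter-peak separation in degrees (default 25).
#' @return A [PeakSet-class] (empty for an all-zero ODF).
#' @export
setGeneric("extractPeaks",
           function(odf, relThreshold = 0.1, minSep = 25)
             standardGeneric("extractPeaks"))
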