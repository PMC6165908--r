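setMethod("show", "CartesianQGrid", function(object) {
  uniq <- uniquePoints(object)
  cat(sprintf(paste0(
    "CartesianQGrid: radius %d (extent %d^3), bMax %g s/mm^2\n",
    "  %d lattice points, %d antipodally unique (%d nonzero)\n"),
    object@radius, 2L * object@radius + 1L, object@bMax,
    nrow(object@points), sum(uniq),
    sum(uniq & rowSums(object@points^2) > 0)))
})

setMethod("show", "SamplingScheme", function(object) {
  e <- object@entries
  b <- sort(unique(round(e$bval[e$bval > 0])))
  cat(sprintf(paste0(
    "SamplingScheme '%s': %d entries (%d DWIs, %d measured, %d b=0)\n",
    "  b-values: %s s/mm^2\n"),
    object@protocolId, nrow(e), sum(e$bval > 0),
    sum(e$bval > 0 & e$measured), sum(e$bval == 0),
    if (length(b) > 6L)
      sprintf("%g-%g (%d distinct)", min(b), max(b), length(b))
    else paste(b, collapse = ", ")))
})

setMethod("show", "ProtocolMeta", function(object) {
  cat(sprintf(
    "ProtocolMeta: TE/TR = %g/%g ms, Delta = %g ms, delta = %g ms, %d b=0\n  effective diffusion time tau = %.4g s\n",
    object@te, object@tr, object@Delta, object@delta, object@nB0,
    diffusionTime(object)))
})

setMethod("show", "Propagator", function(object) {
  conv <- object@info$converged
  cat(sprintf(paste0(
    "Propagator: %d^3 displacement array, mass %.4g\n",
    "  voxel pitch: 1 grid unit%s%s\n"),
    dim(object@values)[1], sum(object@values),
    if (is.na(object@spacingMm)) "" else
      sprintf(" = %.3g mm", object@spacingMm),
    if (is.null(conv)) "" else
      sprintf("; solver converged: %s", conv)))
})

setMethod("show", "DODF", function(object) {
  cat(sprintf("DODF: %d directions, amplitude range [%.3g, %.3g]\n",
              nrow(object@directions), min(object@values),
              max(object@values)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peak(s)\n", nPeaks(object)))
  if (nPeaks(object)) {
    pk <- object@peaks
    for (i in seq_len(nrow(pk)))
      cat(sprintf("  [%d] (%+.3f, %+.3f, %+.3f)  amp %.4g  frac %.3f\n",
                  i, pk$dx[i], pk$dy[i], pk$dz[i], pk$amplitude[i],
                  pk$fraction[i]))
  }
})

setMethod("show", "TensorFit", function(object) {
  cat(sprintf(paste0(
    "TensorFit: FA %.4f, MD %.4g, AD %.4g, RD %.4g mm^2/s\n",
    "  residual NMSE %.3g%s\n"),
    object@fa, object@md, object@ad, object@rd, object@nmse,
    if (object@clamped) " (negative eigenvalues clamped)" else ""))
})

setMethod("show", "KurtosisFit", function(object) {
  cat(sprintf(paste0(
    "KurtosisFit: FA %.4f, MD %.4g mm^2/s; MK %.4f, AK %.4f, RK %.4f\n",
    "  residual NMSE %.3g%s\n"),
    object@fa, object@md, object@mk, object@ak, object@rk, object@nmse,
    if (object@constrained) " (constraints engaged)" else ""))
})

setMethod("show", "ShellAssignment", function(object) {
  cat(sprintf(
    "ShellAssignment: %d shells, max |shift| %.3g s/mm^2\n  centres: %s\n",
    length(object@centers), object@maxAbsShift,
    paste(object@centers, collapse = ", ")))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d compartment(s), S0 = %g, noise sigma = %g\n",
    length(object@compartments), object@S0, object@noiseSigma))
})

setMethod("show", "Dataset", function(object) {
  d <- dim(object@volumes)
  cat(sprintf("Dataset: %d x %d x %d voxels, %d volumes ('%s')%s\n",
              d[1], d[2], d[3], d[4], object@scheme@protocolId,
              if (length(object@mask))
                sprintf(", mask %d voxels", sum(object@mask)) else ""))
})
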