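# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded operations do not perturb the global stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Unit-normalize matrix rows; zero rows stay zero.
normalizeRows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / ifelse(nrm > 0, nrm, 1)
}

# Angle in degrees between direction lines (sign-invariant).
lineAngleDeg <- function(u, v) {
  acos(pmin(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
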