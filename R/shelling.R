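#' Post hoc shell assignment of Cartesian-grid b-values
#'
#' Shell-based preprocessing tools (eddy-current/motion correction with
#' Gaussian-process signal models) require the samples to lie on a small
#' number of b-value shells. Cartesian-grid (DSI) acquisitions do not, so
#' their nominal b-values are shifted - by construction never more than
#' `maxShift` - onto cluster centres found by 1-D agglomerative merging of
#' the distinct nonzero b-values: the closest pair of clusters is merged
#' while every member stays within `maxShift` of the (volume-weighted)
#' cluster mean. b = 0 volumes pass through unchanged. The adjustment is
#' nominal only; keep the original b-values for all downstream computation.
#'
#' On the exact radius-5 grid mapping (b = 6800 |q|^2 / 25) the 22 distinct
#' attainable b-values are farther apart than 50 s/mm^2, so the default
#' bound yields 22 shells with zero shift.
#'
#' @param bvals Numeric vector of b-values (>= 0), one per volume.
#' @param maxShift Hard bound on the absolute nominal shift, s/mm^2
#'   (default 50).
#' @param nShells Optional target shell count: merging continues (still
#'   respecting `maxShift`) until this many clusters remain, or fails with
#'   an error naming the blocking gap.
#' @return A [ShellAssignment-class].
#' @examples
#' assignShells(c(0, 995, 1032, 1990, 2005), maxShift = 50)
#' @export
assignShells <- function(bvals, maxShift = 50, nShells = NULL) {
  if (any(bvals < 0)) stop("b-values must be non-negative")
  nz <- bvals[bvals > 0]
  ub <- sort(unique(nz))
  cnt <- as.numeric(table(factor(nz, levels = ub)))
  # clusters as index ranges over the sorted distinct values
  clusters <- lapply(seq_along(ub), function(i) i)
  clusterStats <- function(cl) {
    v <- ub[cl]; w <- cnt[cl]
    m <- sum(v * w) / sum(w)
    # deviations measured against the exported (rounded) centre so the
    # maxShift bound holds for the reported shifts too
    list(mean = m, maxDev = if (length(v)) max(abs(v - round(m))) else 0)
  }
  repeat {
    if (length(clusters) <= 1L) break
    means <- vapply(clusters, function(cl) clusterStats(cl)$mean, 0)
    gaps <- diff(means)
    ord <- order(gaps)
    merged <- FALSE
    for (k in ord) {
      cand <- c(clusters[[k]], clusters[[k + 1L]])
      if (clusterStats(cand)$maxDev <= maxShift) {
        clusters[[k]] <- cand
        clusters[[k + 1L]] <- NULL
        merged <- TRUE
        break
      }
      # without a target count, only the closest pair is considered
      if (is.null(nShells)) break
    }
    if (!merged) {
      if (!is.null(nShells) && length(clusters) > nShells) {
        k <- ord[1L]
        stop(sprintf(paste0(
          "cannot reach %d shells under maxShift = %g: blocking gap ",
          "between b = %g and b = %g"), nShells, maxShift,
          clusterStats(clusters[[k]])$mean,
          clusterStats(clusters[[k + 1L]])$mean))
      }
      break
    }
    if (!is.null(nShells) && length(clusters) <= nShells) break
  }
  centers <- round(vapply(clusters, function(cl) clusterStats(cl)$mean, 0))
  assignedOf <- numeric(length(ub))
  for (i in seq_along(clusters)) assignedOf[clusters[[i]]] <- centers[i]
  assigned <- bvals
  pos <- match(bvals, ub)
  assigned[bvals > 0] <- assignedOf[pos[bvals > 0]]
  tab <- data.frame(original = bvals, assigned = assigned,
                    shift = assigned - bvals)
  new("ShellAssignment", centers = sort(unique(centers)), table = tab,
      maxAbsShift = if (nrow(tab)) max(abs(tab$shift)) else 0)
}

#' Number of shells in an assignment
#'
#' @param x A [ShellAssignment-class].
#' @return Integer count of shell centres.
#' @export
nShells <- function(x) length(x@centers)
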