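#' Read an FSL-dialect gradient table
#'
#' Reads a `bvals` file (one whitespace-separated row) and a `bvecs` file
#' (three rows: x, y, z; one column per volume) into a sampling scheme.
#' Non-unit direction vectors are normalized with a warning; a zero vector
#' on a b > 0 column is an error; b = 0 columns get zero vectors.
#'
#' @param bvalPath,bvecPath File paths.
#' @param protocolId Label for the resulting scheme.
#' @param meta Optional [ProtocolMeta-class].
#' @return A [SamplingScheme-class] (all entries `measured = TRUE`, no grid
#'   indices).
#' @export
readFslGradients <- function(bvalPath, bvecPath, protocolId = "fsl",
                             meta = NULL) {
  bvals <- scan(bvalPath, quiet = TRUE)
  rows <- readLines(bvecPath)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop("bvecs must have exactly 3 rows, found ", length(rows))
  vec <- lapply(rows, function(r) as.numeric(strsplit(trimws(r),
                                                      "\\s+")[[1]]))
  lens <- vapply(vec, length, 0L)
  if (length(unique(c(lens, length(bvals)))) != 1L)
    stop("row-length mismatch: bvals has ", length(bvals),
         " entries, bvec rows have ", paste(lens, collapse = "/"))
  g <- cbind(vec[[1]], vec[[2]], vec[[3]])
  nrm <- sqrt(rowSums(g^2))
  dw <- bvals > 0
  if (any(dw & nrm < 1e-12))
    stop("zero direction vector on a b > 0 volume")
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    warning("non-unit b-vectors normalized")
    g[dw, ] <- g[dw, ] / nrm[dw]
  }
  g[!dw, ] <- 0
  entries <- data.frame(dx = g[, 1], dy = g[, 2], dz = g[, 3],
                        bval = bvals, qx = NA_integer_, qy = NA_integer_,
                        qz = NA_integer_, measured = TRUE)
  new("SamplingScheme", protocolId = protocolId, entries = entries,
      meta = meta)
}

#' Write a scheme as FSL bval/bvec files
#'
#' Only measured entries are exported (the acquisition view of a CS
#' scheme). b = 0 columns are written as `0 0 0`.
#'
#' @param scheme A [SamplingScheme-class].
#' @param prefix Output path prefix; writes `<prefix>.bval` and
#'   `<prefix>.bvec`.
#' @param measuredOnly Export only `measured = TRUE` entries (default
#'   TRUE).
#' @return Invisibly, the two file paths.
#' @export
writeFslGradients <- function(scheme, prefix, measuredOnly = TRUE) {
  e <- scheme@entries
  if (measuredOnly) e <- e[e$measured, , drop = FALSE]
  bvalPath <- paste0(prefix, ".bval")
  bvecPath <- paste0(prefix, ".bvec")
  writeLines(paste(format(e$bval, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvalPath)
  fmt <- function(v) paste(format(v, trim = TRUE, digits = 10,
                                  scientific = FALSE), collapse = " ")
  writeLines(c(fmt(e$dx), fmt(e$dy), fmt(e$dz)), bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' Read and write scheme JSON files
#'
#' The JSON layout is `{protocol_id, meta, entries: [...]}` with one entry
#' object per volume (direction, bval, grid index, measured flag).
#'
#' @param scheme A [SamplingScheme-class].
#' @param path File path.
#' @return `readScheme`: a [SamplingScheme-class]; `writeScheme`:
#'   invisibly, `path`.
#' @export
writeScheme <- function(scheme, path) {
  meta <- scheme@meta
  obj <- list(
    protocol_id = scheme@protocolId,
    meta = if (is.null(meta)) NULL else
      list(TE = meta@te, TR = meta@tr, Delta = meta@Delta,
           delta = meta@delta, n_b0 = meta@nB0),
    entries = scheme@entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeScheme
#' @export
readScheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- NULL
  if (!is.null(obj$meta))
    meta <- protocolMeta(obj$meta$TE, obj$meta$TR, obj$meta$Delta,
                         obj$meta$delta, obj$meta$n_b0)
  e <- as.data.frame(obj$entries)
  for (col in c("qx", "qy", "qz"))
    e[[col]] <- suppressWarnings(as.integer(e[[col]]))
  new("SamplingScheme", protocolId = obj$protocol_id, entries = e,
      meta = meta)
}

#' Bundle volumes, scheme and mask into a Dataset
#'
#' @param volumes 4D array (x, y, z, volume).
#' @param scheme Matching [SamplingScheme-class].
#' @param mask Optional 3D logical array.
#' @param provenance List of reproducibility metadata.
#' @return A [Dataset-class].
#' @export
dataset <- function(volumes, scheme, mask = NULL, provenance = list()) {
  new("Dataset", volumes = volumes, scheme = scheme,
      mask = if (is.null(mask)) array(logical(0), c(0L, 0L, 0L)) else mask,
      provenance = provenance)
}

#' Read a 4D NIfTI volume into a Dataset
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param scheme The [SamplingScheme-class] describing the volumes; its
#'   length must match the 4th dimension.
#' @param maskPath Optional 3D NIfTI mask (nonzero = inside).
#' @return A [Dataset-class] with the NIfTI header carried in
#'   `provenance$niftiHeader`.
#' @export
readVolume <- function(path, scheme, maskPath = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[4] != nrow(scheme@entries))
    stop("volume count ", dim(arr)[4], " does not match scheme length ",
         nrow(scheme@entries))
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    mask <- array(as.numeric(m) != 0, dim = dim(m))
  }
  dataset(arr, scheme, mask,
          provenance = list(source = path,
                            niftiHeader = RNifti::niftiHeader(img)))
}

#' Write a Dataset (or array) as NIfTI
#'
#' @param x A [Dataset-class] or numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional NIfTI image/header supplying the affine.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(x, path, template = NULL) {
  arr <- if (is(x, "Dataset")) x@volumes else x
  img <- if (is.null(template)) RNifti::asNifti(arr) else
    RNifti::asNifti(arr, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a provenance manifest
#'
#' Records the command, parameters, seeds and input file hashes of a CLI
#' run as JSON, sufficient to reproduce the run.
#'
#' @param path Output JSON path.
#' @param command Command or subcommand name.
#' @param params Named list of parameter values.
#' @param inputs Character vector of input paths (md5-hashed if readable).
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(path, command, params = list(),
                          inputs = character(0)) {
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    "")
  obj <- list(command = command, params = params,
              inputs = as.list(hashes),
              package = as.character(utils::packageVersion("csdsi")),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(path)
}
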