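#' Bucketing specification
#'
#' Defines the fixed-width bucket grid and the solvent exclusion windows used
#' to reduce a spectrum to a feature vector. Buckets are identified by their
#' centre positions `lo, lo + width, ..., hi` (inclusive); a position is
#' dropped when it falls inside any exclusion interval, endpoints included.
#' With the defaults (0.50–9.99 ppm, width 0.01, ethanol windows
#' 0.98–1.35 and 3.43–3.85 ppm, water window 4.78–4.86 ppm) the grid holds
#' 950 positions of which 90 are excluded, leaving 860 retained variables.
#'
#' @slot lo,hi first and last bucket positions (ppm).
#' @slot width bucket width (ppm).
#' @slot exclusions two-column matrix of closed ppm intervals to drop.
#'
#' @seealso [bucketSpec()], [bucketPositions()], [bucketSpectrum()]
#' @export
setClass("BucketSpec",
         representation(lo = "numeric", hi = "numeric", width = "numeric",
                        exclusions = "matrix"))

setValidity("BucketSpec", function(object) {
  msg <- character()
  if (!(object@lo < object@hi)) msg <- c(msg, "'lo' must be < 'hi'")
  if (!(object@width > 0)) msg <- c(msg, "'width' must be > 0")
  ex <- object@exclusions
  if (length(ex)) {
    if (ncol(ex) != 2L) msg <- c(msg, "'exclusions' needs two columns")
    else {
      if (any(ex[, 1] > ex[, 2])) msg <- c(msg, "exclusion lo > hi")
      if (any(ex[, 1] < object@lo | ex[, 2] > object@hi))
        msg <- c(msg, "exclusions must lie within [lo, hi]")
      if (nrow(ex) > 1L) {
        o <- order(ex[, 1])
        if (any(ex[o[-1], 1] <= ex[o[-nrow(ex)], 2]))
          msg <- c(msg, "exclusion intervals must not overlap")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Default solvent exclusion windows (ppm)
#'
#' Ethanol satellite regions 0.98–1.35 and 3.43–3.85 ppm and the residual
#' water region 4.78–4.86 ppm.
#' @return A 3 x 2 numeric matrix of closed intervals.
#' @export
solventExclusions <- function() {
  matrix(c(0.98, 1.35,
           3.43, 3.85,
           4.78, 4.86), ncol = 2, byrow = TRUE,
         dimnames = list(c("ethanol1", "ethanol2", "water"), c("lo", "hi")))
}

#' Construct a BucketSpec
#'
#' @param lo,hi first and last bucket centre positions (ppm).
#' @param width bucket width (ppm).
#' @param exclusions two-column matrix of closed ppm intervals, or `NULL`
#'   for none. Defaults to [solventExclusions()].
#' @return A [BucketSpec-class].
#' @examples
#' length(bucketPositions(bucketSpec()))  # 860
#' @export
bucketSpec <- function(lo = 0.50, hi = 9.99, width = 0.01,
                       exclusions = solventExclusions()) {
  if (is.null(exclusions))
    exclusions <- matrix(numeric(0), ncol = 2)
  new("BucketSpec", lo = lo, hi = hi, width = width,
      exclusions = as.matrix(exclusions))
}

setMethod("show", "BucketSpec", function(object) {
  cat("BucketSpec: δ ", object@lo, "–", object@hi, " ppm, width ",
      object@width, " ppm; ", nrow(object@exclusions),
      " exclusion window(s); ", length(bucketPositions(object)),
      " retained buckets\n", sep = "")
})

## Integer-indexed grid construction avoids cumulative floating-point drift
## along the 0.01-ppm ladder.
fullBucketGrid <- function(spec) {
  n <- round((spec@hi - spec@lo) / spec@width)
  spec@lo + spec@width * (0:n)
}

#' @describeIn bucketPositions retained bucket centres of a specification:
#'   the inclusive grid `lo, lo+width, ..., hi` minus every position falling
#'   inside an exclusion interval (closed endpoints), sorted ascending.
#' @export
setMethod("bucketPositions", "BucketSpec", function(x) {
  pos <- fullBucketGrid(x)
  keep <- !excludedPosition(pos, x)
  pos[keep]
})

excludedPosition <- function(pos, spec) {
  tol <- spec@width * 1e-6
  out <- rep(FALSE, length(pos))
  ex <- spec@exclusions
  if (nrow(ex))
    for (i in seq_len(nrow(ex)))
      out <- out | (pos >= ex[i, 1] - tol & pos <= ex[i, 2] + tol)
  out
}

#' Normalize a spectrum to unit total intensity
#'
#' Scales all intensities by one constant so that the sum over grid points
#' whose shifts lie within `[lo, hi]` of the bucket specification equals 1.
#' Points outside the range are scaled by the same constant. By default the
#' denominator includes grid points inside the solvent exclusion windows
#' (normalization precedes exclusion); set `excludeSolvent = TRUE` to
#' renormalize over the retained regions only.
#'
#' @param s an [NMRSpectrum-class].
#' @param spec a [BucketSpec-class] giving the range (and, when
#'   `excludeSolvent`, the windows to omit from the denominator).
#' @param excludeSolvent logical; omit exclusion-window points from the
#'   normalization denominator. Default `FALSE`.
#' @return The rescaled [NMRSpectrum-class].
#' @export
normalizeTotalIntensity <- function(s, spec = bucketSpec(),
                                    excludeSolvent = FALSE) {
  stopifnot(is(s, "NMRSpectrum"), is(spec, "BucketSpec"))
  inRange <- s@ppm >= spec@lo & s@ppm <= spec@hi
  if (excludeSolvent) {
    ex <- spec@exclusions
    for (i in seq_len(nrow(ex)))
      inRange <- inRange & !(s@ppm >= ex[i, 1] & s@ppm <= ex[i, 2])
  }
  total <- sum(s@intensity[inRange])
  if (!is.finite(total) || total <= 0)
    stop("sample '", s@sampleId, "': nonpositive total intensity over δ ",
         spec@lo, "–", spec@hi, " ppm; cannot normalize")
  initialize(s, intensity = s@intensity / total)
}

#' Reduce a spectrum to its retained-bucket vector
#'
#' Each grid point with shift d is assigned to the bucket position p with
#' p - width/2 <= d < p + width/2 (half-open on the right; the final bucket
#' is closed on the right), and intensities are summed within buckets.
#' Points assigned to excluded positions, or lying outside the bucketed
#' range altogether, do not contribute.
#'
#' @param s an [NMRSpectrum-class], normally already normalized.
#' @param spec a [BucketSpec-class].
#' @return Named numeric vector over retained buckets, in
#'   [bucketPositions()] order; names are positions formatted to the grid
#'   precision.
#' @export
bucketSpectrum <- function(s, spec = bucketSpec()) {
  stopifnot(is(s, "NMRSpectrum"), is(spec, "BucketSpec"))
  tol <- spec@width * 1e-6
  if (min(s@ppm) > spec@lo + tol || max(s@ppm) < spec@hi - tol)
    stop("sample '", s@sampleId, "': spectrum spans δ ",
         format(min(s@ppm)), "–", format(max(s@ppm)),
         " ppm but bucketing needs coverage of δ ", spec@lo, "–", spec@hi,
         " ppm (missing span: ",
         if (min(s@ppm) > spec@lo + tol)
           paste0(spec@lo, "–", format(min(s@ppm))) else "",
         if (min(s@ppm) > spec@lo + tol && max(s@ppm) < spec@hi - tol)
           " and " else "",
         if (max(s@ppm) < spec@hi - tol)
           paste0(format(max(s@ppm)), "–", spec@hi) else "",
         ")")
  full <- fullBucketGrid(spec)
  nFull <- length(full)
  ## index of the bucket whose half-open window holds each point; the 1e-6
  ## (bucket-width units) nudge sends exact-edge points rightward
  ## regardless of floating-point representation
  idx <- floor((s@ppm - (spec@lo - spec@width / 2)) / spec@width + 1e-6) + 1L
  ## final bucket is closed on the right
  idx[abs(s@ppm - (spec@hi + spec@width / 2)) <= tol] <- nFull
  ok <- idx >= 1L & idx <= nFull
  sums <- numeric(nFull)
  if (any(ok)) {
    agg <- rowsum(s@intensity[ok], idx[ok])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  keep <- !excludedPosition(full, spec)
  out <- sums[keep]
  names(out) <- formatC(full[keep], format = "f",
                        digits = max(0, -floor(log10(spec@width))))
  out
}

#' Samples-by-buckets variable table
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with retained buckets
#' as rows (rowData column `ppm`) and samples as columns; the single assay
#' `"intensity"` holds the normalized bucket values. The originating
#' [BucketSpec-class] is kept in `metadata(x)$bucketSpec`. Modeling code
#' consumes the transposed samples-by-buckets view via [bucketMatrix()].
#'
#' @seealso [bucketTable()], [bucketMatrix()], [bucketPositions()]
#' @export
setClass("BucketTable", contains = "SummarizedExperiment")

setValidity("BucketTable", function(object) {
  msg <- character()
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  spec <- S4Vectors::metadata(object)$bucketSpec
  if (is.null(spec) || !is(spec, "BucketSpec"))
    msg <- c(msg, "metadata(x)$bucketSpec must hold the BucketSpec")
  else if (nrow(object) != length(bucketPositions(spec)))
    msg <- c(msg, "row count must equal the retained-bucket count of the spec")
  if (length(msg)) msg else TRUE
})

#' Assemble a BucketTable from raw spectra
#'
#' Applies [normalizeTotalIntensity()] then [bucketSpectrum()] to each
#' spectrum and stacks the results, samples in input order.
#'
#' @param spectra list of [NMRSpectrum-class] with unique sample ids.
#' @param spec a [BucketSpec-class].
#' @param normalize logical; normalize each spectrum first (default `TRUE`).
#' @param excludeSolvent passed to [normalizeTotalIntensity()].
#' @return A [BucketTable-class].
#' @examples
#' cfg <- wineSimConfig(nPerClass = 2L, seed = 1L)
#' ds <- simulateClassificationSet(cfg)
#' bt <- bucketTable(ds$spectra)
#' dim(bucketMatrix(bt))
#' @export
bucketTable <- function(spectra, spec = bucketSpec(), normalize = TRUE,
                        excludeSolvent = FALSE) {
  ids <- vapply(spectra, sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pos <- bucketPositions(spec)
  vals <- matrix(NA_real_, nrow = length(pos), ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (j in seq_along(spectra)) {
    s <- spectra[[j]]
    if (normalize) s <- normalizeTotalIntensity(s, spec, excludeSolvent)
    vals[, j] <- bucketSpectrum(s, spec)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = vals),
    rowData = S4Vectors::DataFrame(ppm = pos))
  S4Vectors::metadata(se)$bucketSpec <- spec
  new("BucketTable", se)
}

#' @describeIn bucketPositions retained bucket centres of a table.
#' @export
setMethod("bucketPositions", "BucketTable",
          function(x) SummarizedExperiment::rowData(x)$ppm)

#' @rdname bucketMatrix
#' @export
setMethod("bucketMatrix", "BucketTable", function(x) {
  m <- t(SummarizedExperiment::assay(x, "intensity"))
  colnames(m) <- formatC(bucketPositions(x), format = "f", digits = 2)
  m
})

setMethod("show", "BucketTable", function(object) {
  cat("BucketTable: ", ncol(object), " sample(s) × ", nrow(object),
      " retained bucket(s)\n", sep = "")
  callNextMethod()
})

#' Write / read a BucketTable as CSV
#'
#' First column `sample_id`, remaining columns the bucket positions
#' formatted to two decimals.
#'
#' @param x a [BucketTable-class].
#' @param file path.
#' @return For the writer, `file` invisibly; for the reader, a list with the
#'   samples-by-buckets `matrix` and the numeric `ppm` positions.
#' @export
writeBucketTableCSV <- function(x, file) {
  m <- bucketMatrix(x)
  d <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeBucketTableCSV
#' @export
readBucketTableCSV <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  list(matrix = m, ppm = as.numeric(colnames(m)))
}
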