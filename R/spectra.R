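#' One-dimensional NMR spectrum
#'
#' Container for a single processed, real-valued 1D spectrum: a strictly
#' monotone chemical-shift axis (ppm) and one intensity value per grid point.
#' Spectra are assumed already referenced (e.g. to TSP at 0 ppm); no phase or
#' baseline handling happens here.
#'
#' @slot sampleId character scalar naming the sample.
#' @slot ppm numeric chemical shifts, strictly monotone (either direction).
#' @slot intensity numeric intensities, same length as `ppm`.
#'
#' @seealso [nmrSpectrum()], [normalizeTotalIntensity()], [bucketSpectrum()]
#' @export
setClass("NMRSpectrum",
         representation(sampleId = "character",
                        ppm = "numeric",
                        intensity = "numeric"))

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-empty string")
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "'ppm' and 'intensity' must have equal length")
  if (length(object@ppm) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 points")
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msg <- c(msg, "'ppm' must be strictly monotone")
  if (anyNA(object@ppm) || anyNA(object@intensity))
    msg <- c(msg, "'ppm' and 'intensity' must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectrum
#'
#' @param sampleId sample name.
#' @param ppm chemical shifts (ppm), strictly monotone.
#' @param intensity intensities, one per shift.
#' @return An [NMRSpectrum-class]. The axis is stored ascending internally;
#'   descending input (NMR display convention) is reversed on construction.
#' @examples
#' s <- nmrSpectrum("a", seq(0.5, 10, by = 0.5), rnorm(20))
#' chemicalShift(s)[1:3]
#' @export
nmrSpectrum <- function(sampleId, ppm, intensity) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) >= 2L && ppm[1] > ppm[length(ppm)]) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  new("NMRSpectrum", sampleId = as.character(sampleId),
      ppm = ppm, intensity = intensity)
}

#' @rdname sampleId
#' @export
setMethod("sampleId", "NMRSpectrum", function(x) x@sampleId)

#' @rdname chemicalShift
#' @export
setMethod("chemicalShift", "NMRSpectrum", function(x) x@ppm)

#' @rdname intensity
#' @export
setMethod("intensity", "NMRSpectrum", function(x) x@intensity)

setMethod("show", "NMRSpectrum", function(object) {
  cat("NMRSpectrum '", object@sampleId, "': ", length(object@ppm),
      " points, δ ", format(min(object@ppm)), "–",
      format(max(object@ppm)), " ppm\n", sep = "")
})

#' Read a spectrum from a two-column CSV
#'
#' Expects columns ppm and intensity, in that order; a header line is
#' auto-detected (treated as present when the first field is not numeric).
#'
#' @param file path to the CSV file.
#' @param sampleId sample name; defaults to the file name without extension.
#' @return An [NMRSpectrum-class].
#' @export
readSpectrumCSV <- function(file, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(file))
  first <- readLines(file, n = 1L)
  hasHeader <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  d <- utils::read.csv(file, header = hasHeader,
                       col.names = c("ppm", "intensity"),
                       colClasses = c("numeric", "numeric"))
  nmrSpectrum(sampleId, d$ppm, d$intensity)
}

#' Write a spectrum as a two-column CSV
#'
#' Written with ppm descending (NMR display convention) and a header line.
#'
#' @param s an [NMRSpectrum-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSpectrumCSV <- function(s, file) {
  o <- order(s@ppm, decreasing = TRUE)
  utils::write.csv(data.frame(ppm = s@ppm[o], intensity = s@intensity[o]),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
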