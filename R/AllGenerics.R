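#' @import methods
NULL

#' Sample identifier of an object
#'
#' @param x an object carrying a sample identifier.
#' @return A character scalar.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' Chemical-shift axis of a spectrum
#'
#' @param x an [NMRSpectrum-class] object.
#' @return Numeric vector of chemical shifts (ppm).
#' @export
setGeneric("chemicalShift", function(x) standardGeneric("chemicalShift"))

#' Intensity values of a spectrum
#'
#' @param x an [NMRSpectrum-class] object.
#' @return Numeric vector of intensities (arbitrary units).
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' Retained bucket positions of a bucketed object
#'
#' @param x a [BucketSpec-class] or [BucketTable-class].
#' @return Numeric vector of retained bucket centre positions (ppm), ascending.
#' @export
setGeneric("bucketPositions", function(x) standardGeneric("bucketPositions"))

#' Samples-by-buckets intensity matrix
#'
#' @param x a [BucketTable-class].
#' @return Numeric matrix, one row per sample, one column per retained bucket.
#' @export
setGeneric("bucketMatrix", function(x) standardGeneric("bucketMatrix"))

#' Number of chosen latent variables
#'
#' @param x a [PLSFit-class].
#' @return Integer component count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Latent-variable scores
#'
#' @param x a [PLSFit-class].
#' @return Numeric matrix of training scores (samples by components).
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Regression coefficient vector on the original variables
#'
#' @param x a [PLSFit-class].
#' @param k number of components to use; defaults to the fitted count.
#' @return Numeric vector of per-variable coefficients (centred scale).
#' @export
setGeneric("regressionCoefficients",
           function(x, k = nComponents(x)) standardGeneric("regressionCoefficients"))
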