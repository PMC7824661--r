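#' Synthetic wine-spectrum configuration
#'
#' Describes a generative model for wine-like 1D 1H NMR data with fully
#' known ground truth: Lorentzian metabolite peaks on a fixed ppm grid,
#' per-class Gaussian concentration distributions (truncated at zero),
#' solvent artifact peaks confined to the ethanol/water exclusion windows,
#' additive Gaussian instrument noise, and quantitative targets that are
#' noisy linear functions of the underlying concentrations.
#'
#' @slot ppmStart,ppmEnd,ppmStep grid of chemical shifts (ppm).
#' @slot peaks data.frame with columns `name`, `center`, `width`
#'   (Lorentzian half-width at half-maximum, ppm) and `area` (dimensionless
#'   multiplier of concentration), one row per metabolite.
#' @slot classes character vector of class labels.
#' @slot classMeans,classSds numeric matrices (classes x metabolites) of
#'   concentration means and standard deviations.
#' @slot nPerClass integer samples per class.
#' @slot artifacts data.frame with columns `center`, `width`, `amplitude`
#'   for solvent peaks (conventionally inside the exclusion windows).
#' @slot noiseSd additive Gaussian intensity noise SD.
#' @slot targetCoefficients numeric, one per metabolite; the quantitative
#'   target is their inner product with the concentration vector.
#' @slot targetNoiseSd Gaussian SD of the target noise.
#' @slot seed integer master seed for the generator.
#'
#' @seealso [wineSimConfig()], [simulateClassificationSet()],
#'   [simulateRegressionSet()]
#' @export
setClass("WineSimConfig",
         representation(ppmStart = "numeric", ppmEnd = "numeric",
                        ppmStep = "numeric", peaks = "data.frame",
                        classes = "character", classMeans = "matrix",
                        classSds = "matrix", nPerClass = "integer",
                        artifacts = "data.frame", noiseSd = "numeric",
                        targetCoefficients = "numeric",
                        targetNoiseSd = "numeric", seed = "integer"))

setValidity("WineSimConfig", function(object) {
  msg <- character()
  p <- object@peaks
  if (!all(c("name", "center", "width", "area") %in% names(p)))
    msg <- c(msg, "'peaks' needs columns name, center, width, area")
  else {
    if (any(p$width <= 0)) msg <- c(msg, "peak widths must be > 0")
    if (any(p$area <= 0)) msg <- c(msg, "peak areas must be > 0")
  }
  if (object@ppmStep <= 0) msg <- c(msg, "'ppmStep' must be > 0")
  if (object@ppmStart >= object@ppmEnd) msg <- c(msg, "empty ppm grid")
  if (length(object@classes) < 1L) msg <- c(msg, "at least one class required")
  if (anyDuplicated(object@classes)) msg <- c(msg, "duplicate class labels")
  nm <- nrow(object@peaks)
  if (!all(dim(object@classMeans) == c(length(object@classes), nm)))
    msg <- c(msg, "'classMeans' must be classes x metabolites")
  if (!all(dim(object@classSds) == dim(object@classMeans)))
    msg <- c(msg, "'classSds' must match 'classMeans'")
  if (any(object@classMeans < 0))
    msg <- c(msg, "concentration means must be >= 0")
  if (any(object@classSds < 0)) msg <- c(msg, "'classSds' must be >= 0")
  if (object@nPerClass < 1L) msg <- c(msg, "'nPerClass' must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(object@targetCoefficients) != nm)
    msg <- c(msg, "'targetCoefficients' needs one value per metabolite")
  if (object@targetNoiseSd < 0) msg <- c(msg, "'targetNoiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Default synthetic metabolite peaks
#'
#' Eight abstract peaks spread over δ 0.9–9.3 ppm, placed outside the
#' solvent exclusion windows so their signal survives bucketing.
#' @return data.frame with columns name, center, width, area.
#' @export
defaultPeaks <- function() {
  data.frame(
    name   = paste0("m", 1:8),
    center = c(0.90, 1.55, 2.40, 3.20, 4.30, 5.90, 7.40, 9.30),
    width  = rep(0.008, 8),
    area   = c(1.0, 0.8, 1.2, 0.6, 1.0, 0.9, 0.7, 1.1))
}

#' Default solvent artifact peaks
#'
#' Large peaks standing in for the ethanol CH3/CH2 satellites and residual
#' water, centred inside the three exclusion windows.
#' @return data.frame with columns center, width, amplitude.
#' @export
defaultArtifacts <- function() {
  data.frame(center = c(1.17, 3.65, 4.82),
             width = c(0.010, 0.010, 0.012),
             amplitude = c(40, 60, 100))
}

#' Construct a WineSimConfig
#'
#' The defaults define a three-class, well-separated recovery scenario:
#' two metabolites per non-reference class are shifted by five concentration
#' standard deviations, instrument noise is small relative to peak heights,
#' and the quantitative target loads on four of the eight metabolites.
#'
#' @param ppmStart,ppmEnd,ppmStep chemical-shift grid (ppm).
#' @param peaks metabolite peak table, as [defaultPeaks()].
#' @param classes class labels.
#' @param classMeans,classSds concentration means/SDs (classes x peaks);
#'   defaults separate the classes by 5 SD on two metabolites each.
#' @param nPerClass samples per class.
#' @param artifacts solvent peak table, as [defaultArtifacts()]; pass a
#'   zero-row data.frame for none.
#' @param noiseSd additive intensity noise SD.
#' @param targetCoefficients linear map from concentrations to the target.
#' @param targetNoiseSd target noise SD.
#' @param seed integer master seed.
#' @return A [WineSimConfig-class].
#' @export
wineSimConfig <- function(ppmStart = 0.5, ppmEnd = 10.0, ppmStep = 0.001,
                          peaks = defaultPeaks(),
                          classes = c("varietyA", "varietyB", "varietyC"),
                          classMeans = NULL, classSds = NULL,
                          nPerClass = 40L,
                          artifacts = defaultArtifacts(),
                          noiseSd = 0.05,
                          targetCoefficients = NULL,
                          targetNoiseSd = 0.1,
                          seed = 1L) {
  nm <- nrow(peaks)
  if (is.null(classMeans)) {
    base <- rep_len(c(5, 3, 8, 2, 6, 4, 7, 3), nm)
    classMeans <- matrix(rep(base, each = length(classes)),
                         nrow = length(classes),
                         dimnames = list(classes, peaks$name))
    if (length(classes) >= 2L && nm >= 4L)
      classMeans[2, c(1, 4)] <- classMeans[2, c(1, 4)] + 2.5
    if (length(classes) >= 3L && nm >= 6L)
      classMeans[3, c(2, 6)] <- classMeans[3, c(2, 6)] + 2.5
  }
  if (is.null(classSds))
    classSds <- matrix(0.5, nrow(classMeans), ncol(classMeans),
                       dimnames = dimnames(classMeans))
  if (is.null(targetCoefficients))
    targetCoefficients <- rep_len(c(0.8, 0, 1.5, 0, 0, 2.0, 0, 0.5), nm)
  if (is.null(artifacts))
    artifacts <- data.frame(center = numeric(0), width = numeric(0),
                            amplitude = numeric(0))
  new("WineSimConfig", ppmStart = ppmStart, ppmEnd = ppmEnd,
      ppmStep = ppmStep, peaks = peaks, classes = as.character(classes),
      classMeans = as.matrix(classMeans), classSds = as.matrix(classSds),
      nPerClass = as.integer(nPerClass), artifacts = artifacts,
      noiseSd = noiseSd, targetCoefficients = targetCoefficients,
      targetNoiseSd = targetNoiseSd, seed = as.integer(seed))
}

setMethod("show", "WineSimConfig", function(object) {
  cat("WineSimConfig: ", nrow(object@peaks), " metabolite peak(s), ",
      length(object@classes), " class(es) × ", object@nPerClass,
      " sample(s), grid δ ", object@ppmStart, "–", object@ppmEnd,
      " step ", object@ppmStep, " ppm, noiseSd ", object@noiseSd,
      ", seed ", object@seed, "\n", sep = "")
})

simGrid <- function(config) {
  n <- round((config@ppmEnd - config@ppmStart) / config@ppmStep)
  config@ppmStart + config@ppmStep * (0:n)
}

## Evaluate the RNG-consuming part of simulation under a seed while leaving
## the caller's RNG state untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic noiseless mixture spectrum; errors if any peak centre is
## off-grid so misconfigured simulations fail loudly.
mixtureIntensity <- function(config, concentrations, grid) {
  pk <- config@peaks
  if (length(concentrations) != nrow(pk))
    stop("need one concentration per metabolite (",
         nrow(pk), "), got ", length(concentrations))
  if (any(concentrations < 0))
    stop("concentrations must be nonnegative")
  lo <- min(grid); hi <- max(grid)
  off <- pk$center < lo | pk$center > hi
  if (any(off))
    stop("peak(s) outside the ppm grid: ",
         paste(pk$name[off], collapse = ", "))
  a <- config@artifacts
  if (nrow(a) && any(a$center < lo | a$center > hi))
    stop("solvent artifact peak outside the ppm grid")
  y <- numeric(length(grid))
  for (m in seq_len(nrow(pk)))
    if (concentrations[m] > 0)
      y <- y + concentrations[m] * pk$area[m] *
        stats::dcauchy(grid, pk$center[m], pk$width[m])
  for (j in seq_len(nrow(a)))
    y <- y + a$amplitude[j] * stats::dcauchy(grid, a$center[j], a$width[j])
  y
}

#' Simulate one spectrum from known concentrations
#'
#' Intensity at shift d is the concentration-weighted sum of Lorentzian
#' densities (HWHM parameterization) plus solvent artifact peaks plus
#' additive Gaussian noise; noise may push intensities slightly negative.
#'
#' @param config a [WineSimConfig-class].
#' @param concentrations nonnegative vector, one value per metabolite peak.
#' @param seed integer seed for the noise draw.
#' @param sampleIdName sample name for the result.
#' @return An [NMRSpectrum-class] on the configured grid.
#' @examples
#' cfg <- wineSimConfig(artifacts = NULL, noiseSd = 0)
#' s <- simulateSpectrum(cfg, rep(1, 8), seed = 1L)
#' @export
simulateSpectrum <- function(config, concentrations, seed,
                             sampleIdName = "sim") {
  grid <- simGrid(config)
  y <- mixtureIntensity(config, concentrations, grid)
  if (config@noiseSd > 0)
    y <- y + withSeed(as.integer(seed),
                      stats::rnorm(length(grid), 0, config@noiseSd))
  nmrSpectrum(sampleIdName, grid, y)
}

## One truncated-Gaussian concentration vector (redraw negatives).
drawConcentrations <- function(mu, sd) {
  conc <- stats::rnorm(length(mu), mu, sd)
  bad <- conc < 0
  while (any(bad)) {
    conc[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    bad <- conc < 0
  }
  conc
}

simulateSamples <- function(config) {
  grid <- simGrid(config)
  nc <- length(config@classes)
  n <- nc * config@nPerClass
  withSeed(config@seed, {
    rows <- vector("list", n)
    spectra <- vector("list", n)
    k <- 0L
    for (ci in seq_len(nc)) {
      for (i in seq_len(config@nPerClass)) {
        k <- k + 1L
        conc <- drawConcentrations(config@classMeans[ci, ],
                                   config@classSds[ci, ])
        y <- mixtureIntensity(config, conc, grid)
        if (config@noiseSd > 0)
          y <- y + stats::rnorm(length(grid), 0, config@noiseSd)
        id <- sprintf("s%03d_%s", k, config@classes[ci])
        spectra[[k]] <- nmrSpectrum(id, grid, y)
        rows[[k]] <- data.frame(sample_id = id,
                                class = config@classes[ci],
                                t(stats::setNames(conc,
                                                  config@peaks$name)))
      }
    }
    truth <- do.call(rbind, rows)
    truth$target <- as.numeric(as.matrix(truth[, config@peaks$name]) %*%
                                 config@targetCoefficients)
    if (config@targetNoiseSd > 0)
      truth$target <- truth$target +
        stats::rnorm(n, 0, config@targetNoiseSd)
    truth$seed <- config@seed
    list(spectra = spectra, truth = truth)
  })
}

#' Simulate a labelled classification dataset
#'
#' Draws `nPerClass` concentration vectors per class from the configured
#' truncated Gaussians and renders one spectrum per sample. Regenerating
#' with the same configuration (including its seed) reproduces the dataset
#' bit-identically.
#'
#' @param config a [WineSimConfig-class] with at least two classes.
#' @return List with `spectra` (list of [NMRSpectrum-class]), `labels`
#'   (factor aligned with `spectra`), and `truth` (data.frame of per-sample
#'   concentrations, class, target and seed).
#' @export
simulateClassificationSet <- function(config) {
  if (length(config@classes) < 2L)
    stop("classification needs at least two classes")
  sim <- simulateSamples(config)
  list(spectra = sim$spectra,
       labels = factor(sim$truth$class, levels = config@classes),
       truth = sim$truth)
}

#' Simulate a regression dataset
#'
#' Same generative model as [simulateClassificationSet()]; the response is
#' the configured linear function of the concentration vector plus Gaussian
#' noise of SD `targetNoiseSd`.
#'
#' @param config a [WineSimConfig-class].
#' @return List with `spectra`, `targets` (numeric, aligned) and `truth`.
#' @export
simulateRegressionSet <- function(config) {
  sim <- simulateSamples(config)
  list(spectra = sim$spectra,
       targets = sim$truth$target,
       truth = sim$truth)
}

#' Write a simulated dataset to disk
#'
#' One two-column CSV per spectrum (ppm descending), a `samples.csv`
#' metadata table (sample_id, class, target, file) and a `manifest.json`
#' recording the seed and per-file MD5 checksums.
#'
#' @param dataset result of [simulateClassificationSet()] or
#'   [simulateRegressionSet()].
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
writeSimulatedDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$spectra))
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    files[i] <- paste0(sampleId(s), ".csv")
    writeSpectrumCSV(s, file.path(dir, files[i]))
  }
  meta <- data.frame(sample_id = dataset$truth$sample_id,
                     class = if ("class" %in% names(dataset$truth))
                       dataset$truth$class else NA,
                     target = dataset$truth$target,
                     file = files)
  utils::write.csv(meta, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(seed = dataset$truth$seed[1],
                   n_samples = nrow(meta),
                   checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
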