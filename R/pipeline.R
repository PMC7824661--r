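#' Build a WineSimConfig from a plain list (e.g. parsed YAML)
#'
#' Recognised keys mirror the [wineSimConfig()] arguments: `ppmStart`,
#' `ppmEnd`, `ppmStep`, `classes`, `nPerClass`, `noiseSd`,
#' `targetNoiseSd`, `seed`, `targetCoefficients`, plus optional `peaks`,
#' `classMeans`, `classSds`, `artifacts` tables. Unknown keys error.
#'
#' @param lst named list (for instance from `yaml::read_yaml()`).
#' @return A [WineSimConfig-class].
#' @export
wineSimConfigFromList <- function(lst) {
  known <- c("ppmStart", "ppmEnd", "ppmStep", "peaks", "classes",
             "classMeans", "classSds", "nPerClass", "artifacts",
             "noiseSd", "targetCoefficients", "targetNoiseSd", "seed")
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("unknown simulation config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(lst$peaks)) lst$peaks <- as.data.frame(lst$peaks)
  if (!is.null(lst$artifacts))
    lst$artifacts <- as.data.frame(lst$artifacts)
  if (!is.null(lst$classMeans)) lst$classMeans <- t(simplify2array(lst$classMeans))
  if (!is.null(lst$classSds)) lst$classSds <- t(simplify2array(lst$classSds))
  do.call(wineSimConfig, lst)
}

#' Simulate a dataset and write it to disk
#'
#' @param config a [WineSimConfig-class], a list, or a YAML file path.
#' @param dir output directory.
#' @param kind `"classification"` or `"regression"` (changes nothing about
#'   the files; both class and target are always recorded).
#' @return Path of the written manifest, invisibly.
#' @export
simulateDataset <- function(config, dir, kind = "classification") {
  config <- resolveSimConfig(config)
  ds <- if (kind == "regression") simulateRegressionSet(config)
        else simulateClassificationSet(config)
  writeSimulatedDataset(ds, dir)
}

resolveSimConfig <- function(config) {
  if (is(config, "WineSimConfig")) return(config)
  if (is.character(config) && length(config) == 1L)
    return(wineSimConfigFromList(yaml::read_yaml(config)))
  if (is.list(config)) return(wineSimConfigFromList(config))
  stop("cannot interpret 'config' as a simulation configuration")
}

#' Load a directory of spectrum CSVs with its samples.csv metadata
#'
#' @param dir directory holding one two-column CSV per spectrum and a
#'   `samples.csv` with columns sample_id, class, target, file.
#' @return List with `spectra` (list of [NMRSpectrum-class]), `labels`
#'   (named character or NA), `targets` (named numeric or NA), `meta`.
#' @export
loadSpectraDir <- function(dir) {
  metaPath <- file.path(dir, "samples.csv")
  if (!file.exists(metaPath))
    stop("missing metadata table: ", metaPath)
  meta <- utils::read.csv(metaPath)
  spectra <- lapply(seq_len(nrow(meta)), function(i)
    readSpectrumCSV(file.path(dir, meta$file[i]),
                    sampleId = meta$sample_id[i]))
  list(spectra = spectra,
       labels = stats::setNames(as.character(meta$class), meta$sample_id),
       targets = stats::setNames(suppressWarnings(as.numeric(meta$target)),
                                 meta$sample_id),
       meta = meta)
}

#' End-to-end classification workflow
#'
#' Preprocess (normalize + bucket) if raw spectra are given, outer
#' stratified split, optional genetic-algorithm variable selection on the
#' outer training set only, iterative double cross-validation, and an
#' optional response-permutation test whose statistic re-runs the whole
#' pipeline (GA included) on shuffled labels and returns the CV-tier
#' weighted AUC.
#'
#' @param table a [BucketTable-class] or samples-by-variables matrix;
#'   alternatively pass `spectra` (list of [NMRSpectrum-class]) to be
#'   bucketed with `bucketSpecObj`.
#' @param labels class labels named by sample id.
#' @param spectra optional raw spectra (used when `table` is `NULL`).
#' @param bucketSpecObj a [bucketSpec()] for preprocessing.
#' @param outerTrainFrac outer stratified split ratio (default 0.8).
#' @param dcvCfg a [doubleCVConfig()].
#' @param gaCfg optional [gaConfig()] (classification fitness); `NULL`
#'   skips selection.
#' @param nPermutations permutation-test iterations; 0 skips the test.
#' @param permutationFreezeMask reuse the observed GA mask inside the
#'   permutation null instead of re-selecting per permutation. Faster but
#'   anti-conservative; a warning is issued.
#' @param seed master seed for the outer split and permutation engine.
#' @param out optional path; the report is written there as JSON.
#' @return List of class `classificationReport`: `metrics` (per tier),
#'   `meanProb`, `mask` (or NULL), `nSelected`, `permutation`, `plan`,
#'   `config` echo, `seed`.
#' @export
runClassificationWorkflow <- function(table = NULL, labels, spectra = NULL,
                                      bucketSpecObj = bucketSpec(),
                                      outerTrainFrac = 0.8,
                                      dcvCfg = doubleCVConfig(),
                                      gaCfg = NULL, nPermutations = 0L,
                                      permutationFreezeMask = FALSE,
                                      seed = 1L, out = NULL) {
  if (is.null(table)) {
    if (is.null(spectra)) stop("supply either 'table' or 'spectra'")
    table <- bucketTable(spectra, bucketSpecObj)
  }
  X <- if (is(table, "BucketTable")) bucketMatrix(table) else as.matrix(table)
  labels <- stats::setNames(as.character(labels[rownames(X)]), rownames(X))
  plan <- stratifiedSplit(labels, trainFrac = outerTrainFrac, seed = seed)
  fitGA <- function(lab) {
    if (is.null(gaCfg)) return(NULL)
    runGA(X[plan$trainIds, , drop = FALSE], lab[plan$trainIds],
          cfg = gaCfg, learner = dcvCfg$learner)
  }
  runOnce <- function(lab, mask) {
    Xm <- if (is.null(mask)) X else X[, mask, drop = FALSE]
    runDoubleCV(Xm, lab, cfg = dcvCfg, plan = plan)
  }
  ga <- fitGA(labels)
  dcv <- runOnce(labels, ga$mask)
  perm <- NULL
  if (nPermutations > 0L) {
    if (permutationFreezeMask && !is.null(gaCfg))
      warning("permutation null reuses the observed variable mask; ",
              "p-values will be anti-conservative")
    pipe <- function(lab) {
      lab <- stats::setNames(as.character(lab), names(labels))
      mask <- if (permutationFreezeMask) ga$mask else fitGA(lab)$mask
      runOnce(lab, mask)$metrics$cv$weightedAUC
    }
    perm <- permutationTest(pipe, labels,
                            nPermutations = nPermutations,
                            seed = as.integer(seed) + 500000L)
  }
  report <- structure(
    list(metrics = dcv$metrics, meanProb = dcv$meanProb,
         predictions = dcv$predictions,
         mask = ga$mask, nSelected = ga$nSelected,
         gaTrajectory = ga$trajectory,
         permutation = perm, plan = plan,
         config = list(outerTrainFrac = outerTrainFrac, dcv = dcvCfg,
                       ga = gaCfg, nPermutations = nPermutations,
                       seed = as.integer(seed)),
         seed = as.integer(seed)),
    class = "classificationReport")
  if (!is.null(out)) writeReportJSON(report, out)
  report
}

#' End-to-end regression workflow
#'
#' Preprocess if needed, chronological external split, optional GA variable
#' selection on the training set, Hotelling T-squared outlier exclusion on
#' a preliminary two-component fit, RMSECV curve with repeated randomized
#' cross-validation, component selection by the first-local-minimum /
#' 2%-improvement rule, final fit, tiered evaluation, and an optional
#' permutation test whose statistic re-runs the training pipeline on
#' shuffled targets and returns the negative RMSECV at the re-chosen
#' component count.
#'
#' @param table,spectra,bucketSpecObj as in [runClassificationWorkflow()].
#' @param targets numeric targets named by sample id.
#' @param nTest trailing samples held out chronologically.
#' @param gaCfg optional [gaConfig()] with `fitness = "cv-rmse"`.
#' @param kMax,cvFolds,cvIterations,improvement RMSECV settings (defaults
#'   20, 5, 20, 0.02).
#' @param outlierConfidence Hotelling ellipse coverage; `NA` skips
#'   exclusion.
#' @param nPermutations permutation iterations; 0 skips.
#' @param permutationFreezeMask as in [runClassificationWorkflow()].
#' @param seed master seed.
#' @param out optional JSON report path.
#' @return List of class `regressionReport`: `eval`
#'   (a `regressionEvalReport`), `k`, `curve`, `outliers`, `mask`,
#'   `nSelected`, `permutation`, `plan`, `config`, `seed`.
#' @export
runRegressionWorkflow <- function(table = NULL, targets, spectra = NULL,
                                  bucketSpecObj = bucketSpec(),
                                  nTest, gaCfg = NULL, kMax = 20L,
                                  cvFolds = 5L, cvIterations = 20L,
                                  improvement = 0.02,
                                  outlierConfidence = 0.95,
                                  nPermutations = 0L,
                                  permutationFreezeMask = FALSE,
                                  seed = 1L, out = NULL) {
  if (is.null(table)) {
    if (is.null(spectra)) stop("supply either 'table' or 'spectra'")
    table <- bucketTable(spectra, bucketSpecObj)
  }
  X <- if (is(table, "BucketTable")) bucketMatrix(table) else as.matrix(table)
  ids <- rownames(X)
  y <- stats::setNames(as.numeric(targets[ids]), ids)
  if (anyNA(y)) stop("missing target value(s) for some samples")
  plan <- chronologicalSplit(ids, nTest)
  trainPipeline <- function(yTrain) {
    trIds <- plan$trainIds
    mask <- NULL; gaRes <- NULL
    if (!is.null(gaCfg)) {
      gaRes <- runGA(X[trIds, , drop = FALSE], yTrain, cfg = gaCfg)
      mask <- gaRes$mask
    }
    Xtr <- if (is.null(mask)) X[trIds, , drop = FALSE]
           else X[trIds, mask, drop = FALSE]
    outliers <- NULL
    if (!is.na(outlierConfidence)) {
      pre <- suppressWarnings(fitPLS(Xtr, yTrain,
                                     k = min(2L, nrow(Xtr) - 1L,
                                             ncol(Xtr))))
      sc <- scores(pre)
      if (ncol(sc) >= 2L) {
        outliers <- detectOutliers(sc, confidence = outlierConfidence,
                                   ids = trIds)
        keep <- !(trIds %in% outliers$excludedIds)
        Xtr <- Xtr[keep, , drop = FALSE]
        yTrain <- yTrain[keep]
        trIds <- trIds[keep]
      }
    }
    curve <- suppressWarnings(
      rmsecvCurve(Xtr, yTrain, kMax = kMax, folds = cvFolds,
                  nIterations = cvIterations,
                  seed = as.integer(seed) + 10000L))
    k <- selectComponents(curve, improvement = improvement, kMax = kMax)
    fit <- suppressWarnings(fitPLS(Xtr, yTrain, k = k))
    k <- min(k, nComponents(fit))
    list(fit = fit, k = k, curve = curve, mask = mask, ga = gaRes,
         outliers = outliers, Xtr = Xtr, yTrain = yTrain, trIds = trIds)
  }
  obs <- trainPipeline(y[plan$trainIds])
  perm <- NULL
  if (nPermutations > 0L) {
    if (permutationFreezeMask && !is.null(gaCfg))
      warning("permutation null reuses the observed variable mask; ",
              "p-values will be anti-conservative")
    basePipe <- trainPipeline
    if (permutationFreezeMask) {
      frozenMask <- obs$mask
      basePipe <- function(yTrain) {
        res <- NULL
        Xtr <- if (is.null(frozenMask)) X[plan$trainIds, , drop = FALSE]
               else X[plan$trainIds, frozenMask, drop = FALSE]
        curve <- suppressWarnings(
          rmsecvCurve(Xtr, yTrain, kMax = kMax, folds = cvFolds,
                      nIterations = cvIterations,
                      seed = as.integer(seed) + 10000L))
        list(curve = curve,
             k = selectComponents(curve, improvement = improvement,
                                  kMax = kMax))
      }
    }
    pipe <- function(yTrain) {
      res <- basePipe(yTrain)
      -res$curve$rmsecv[res$k]
    }
    perm <- permutationTest(pipe, y[plan$trainIds],
                            nPermutations = nPermutations,
                            seed = as.integer(seed) + 500000L)
  }
  maskCols <- if (is.null(obs$mask)) rep(TRUE, ncol(X)) else obs$mask
  XTest <- X[plan$testIds, maskCols, drop = FALSE]
  eval <- suppressWarnings(
    evaluateRegression(obs$fit, obs$Xtr, obs$yTrain,
                       XTest = if (length(plan$testIds)) XTest else NULL,
                       yTest = if (length(plan$testIds)) y[plan$testIds]
                               else NULL,
                       curve = obs$curve, k = obs$k, permutation = perm))
  report <- structure(
    list(eval = eval, k = obs$k, curve = obs$curve,
         outliers = obs$outliers, mask = obs$mask,
         nSelected = if (is.null(obs$mask)) ncol(X) else sum(obs$mask),
         permutation = perm, plan = plan,
         config = list(nTest = nTest, kMax = kMax, cvFolds = cvFolds,
                       cvIterations = cvIterations,
                       improvement = improvement,
                       outlierConfidence = outlierConfidence,
                       ga = gaCfg, nPermutations = nPermutations,
                       seed = as.integer(seed)),
         seed = as.integer(seed)),
    class = "regressionReport")
  if (!is.null(out)) writeReportJSON(report, out)
  report
}

#' Serialize a workflow report to JSON
#'
#' Matrices become row-named lists; functions and S4 payloads that do not
#' serialize (e.g. the learner's `fitFun`) are dropped.
#'
#' @param report a workflow report list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  clean <- rapply(unclass(report), function(x)
    if (is.function(x)) NULL else x,
    how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
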