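#' Stratified train/test split with largest-remainder allocation
#'
#' The total training size is `floor(trainFrac * n)`. Per-class training
#' counts are the floors of the per-class quotas `trainFrac * n_c`, with the
#' remaining seats assigned to the classes with the largest fractional
#' remainders (ties broken by class order). Membership within a class is
#' random under `seed`. With three classes this reproduces 102/26 from
#' n = 128 and 97/25 from n = 122 at an 80% ratio.
#'
#' @param labels factor or character vector of class labels, named by
#'   sample id (or with ids supplied via `ids`).
#' @param trainFrac fraction of samples to train on (default 0.8).
#' @param seed integer seed.
#' @param ids sample ids; defaults to `names(labels)` or seq_along.
#' @return List of class `splitPlan`: `trainIds`, `testIds`, `trainFrac`,
#'   `seed`, and the per-class allocation table.
#' @export
stratifiedSplit <- function(labels, trainFrac = 0.8, seed = 1L, ids = NULL) {
  if (is.null(ids)) ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids),
            trainFrac > 0, trainFrac < 1)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 members; offending class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  nTrain <- floor(trainFrac * length(ids))
  alloc <- largestRemainder(trainFrac * as.numeric(counts), nTrain)
  names(alloc) <- names(counts)
  trainIds <- withSeed(as.integer(seed), {
    unlist(lapply(names(counts), function(cl) {
      member <- ids[labels == cl]
      sample(member, alloc[[cl]])
    }), use.names = FALSE)
  })
  trainIds <- ids[ids %in% trainIds]   # keep input order
  structure(list(trainIds = trainIds,
                 testIds = setdiff(ids, trainIds),
                 trainFrac = trainFrac, seed = as.integer(seed),
                 allocation = alloc),
            class = "splitPlan")
}

## floors of quotas, then +1 seats by decreasing fractional remainder until
## the target total is reached; ties by position
largestRemainder <- function(quotas, total) {
  base <- floor(quotas)
  rem <- quotas - base
  extra <- total - sum(base)
  if (extra > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(extra)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' @export
print.splitPlan <- function(x, ...) {
  cat("splitPlan: ", length(x$trainIds), " train / ", length(x$testIds),
      " test (trainFrac ", x$trainFrac, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Chronological train/test split
#'
#' The last `nTest` ids in the given order form the external test set; all
#' earlier samples train. Used for the regression tasks, where the external
#' set is put aside by sample chronology before any modeling.
#'
#' @param ids ordered sample ids.
#' @param nTest number of trailing samples to hold out.
#' @return List of class `splitPlan` with `trainIds` and `testIds`.
#' @export
chronologicalSplit <- function(ids, nTest) {
  n <- length(ids)
  if (nTest >= n) stop("'nTest' must be smaller than the number of samples")
  if (nTest < 0) stop("'nTest' must be nonnegative")
  idx <- seq_len(n)
  structure(list(trainIds = ids[idx <= n - nTest],
                 testIds = if (nTest > 0) ids[idx > n - nTest]
                           else character(0),
                 trainFrac = (n - nTest) / n, seed = NA_integer_,
                 allocation = NULL),
            class = "splitPlan")
}

#' Configuration of the iterative double cross-validation workflow
#'
#' @param nIterations number of inner resampling iterations (default 50).
#' @param innerTrainFrac fraction of the outer training set used for
#'   calibration in each iteration (default 0.70; the rest is the internal
#'   test set).
#' @param cvFolds stratified cross-validation folds within the inner
#'   training set (default 5).
#' @param learner a [learnerSpec()] for the probabilistic base learner.
#' @param masterSeed integer; iteration i uses seed `masterSeed + i`.
#' @return List of class `doubleCVConfig`.
#' @export
doubleCVConfig <- function(nIterations = 50L, innerTrainFrac = 0.70,
                           cvFolds = 5L, learner = learnerSpec(),
                           masterSeed = 1L) {
  stopifnot(nIterations >= 1L, cvFolds >= 2L,
            innerTrainFrac > 0, innerTrainFrac < 1)
  structure(list(nIterations = as.integer(nIterations),
                 innerTrainFrac = innerTrainFrac,
                 cvFolds = as.integer(cvFolds), learner = learner,
                 masterSeed = as.integer(masterSeed)),
            class = "doubleCVConfig")
}

## Stratified fold labels: within each class, shuffle then deal round-robin,
## so per-class fold sizes differ by at most one.
stratifiedFolds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  assign <- integer(length(labels))
  withSeed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Build the inner iteration plans of a double-CV run
#'
#' For each iteration i (seeded `masterSeed + i`) the outer training set is
#' split 70/30 into inner-train and internal-test sets with stratified
#' sampling, and the inner-train samples get a stratified fold assignment.
#'
#' @param plan an outer [stratifiedSplit()] plan.
#' @param labels class labels named by sample id (covering the outer
#'   training ids).
#' @param cfg a [doubleCVConfig()].
#' @return List of plans; each holds `iteration`, `innerTrainIds`,
#'   `innerTestIds`, `foldAssignment` (named integer vector over
#'   `innerTrainIds`) and `seed`.
#' @export
makeInnerPlans <- function(plan, labels, cfg = doubleCVConfig()) {
  ids <- plan$trainIds
  lab <- as.character(labels[ids])
  minClass <- min(table(lab))
  if (floor(cfg$innerTrainFrac * minClass) < cfg$cvFolds &&
      ceiling(cfg$innerTrainFrac * minClass) < cfg$cvFolds)
    stop("outer training set too small for ", cfg$cvFolds,
         "-fold stratified CV; smallest class has ", minClass, " sample(s)")
  lapply(seq_len(cfg$nIterations), function(i) {
    seedI <- cfg$masterSeed + i
    inner <- stratifiedSplit(stats::setNames(lab, ids),
                             trainFrac = cfg$innerTrainFrac, seed = seedI)
    fold <- stratifiedFolds(labels[inner$trainIds], cfg$cvFolds,
                            seed = seedI + 1000L)
    names(fold) <- inner$trainIds
    list(iteration = i, innerTrainIds = inner$trainIds,
         innerTestIds = inner$testIds, foldAssignment = fold, seed = seedI)
  })
}
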