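#' Classification accuracy
#'
#' @param truth true labels.
#' @param predicted predicted labels, same length.
#' @return Proportion of exact matches.
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty label vectors")
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  mean(as.character(truth) == as.character(predicted))
}

#' Binary AUC by the rank (Mann-Whitney) formulation
#'
#' The probability that a uniformly chosen positive sample outscores a
#' uniformly chosen negative one, ties counted one half.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param positive logical vector (TRUE = positive class), same length.
#' @return AUC in \[0, 1\].
#' @export
aucBinary <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted one-vs-rest multiclass AUC
#'
#' Per-class AUC uses that class's probability column against a one-vs-rest
#' dichotomy; the summary AUC is the mean weighted by class sample counts.
#'
#' @param prob numeric matrix of class probabilities, columns named by
#'   class and covering every observed class.
#' @param labels observed class labels, one per row of `prob`.
#' @return List with `weighted` (scalar) and `perClass` (named vector).
#' @export
weightedMulticlassAUC <- function(prob, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  missing <- setdiff(classes, colnames(prob))
  if (length(missing))
    stop("probability matrix lacks column(s) for class(es): ",
         paste(missing, collapse = ", "))
  per <- vapply(classes, function(cl)
    aucBinary(prob[, cl], labels == cl), numeric(1))
  w <- as.numeric(table(labels)[classes])
  list(weighted = sum(per * w) / sum(w), perClass = per)
}

#' Root mean squared error
#'
#' @param truth,predicted numeric vectors of equal nonzero length.
#' @return `sqrt(mean((truth - predicted)^2))`.
#' @export
rmse <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  sqrt(mean((truth - predicted)^2))
}

#' Coefficient of determination about a reference mean
#'
#' `1 - SSE/SST` with the total sum of squares taken about `referenceMean`.
#' For calibration this is the tier's own mean; for CV and external tiers
#' the training mean is the honest reference.
#'
#' @param truth,predicted numeric vectors of equal nonzero length.
#' @param referenceMean centre of the total sum of squares; defaults to
#'   `mean(truth)`.
#' @return R-squared (can be negative for predictors worse than the mean).
#' @export
rSquared <- function(truth, predicted, referenceMean = mean(truth)) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  sst <- sum((truth - referenceMean)^2)
  if (sst <= 0)
    stop("zero total sum of squares about the reference mean; ",
         "R-squared is undefined (constant response?)")
  1 - sum((truth - predicted)^2) / sst
}

#' Response-permutation (randomization) test
#'
#' Re-runs a full modeling pipeline on response-shuffled data to build a
#' null distribution of its performance statistic. The response vector is
#' permuted uniformly at random each iteration while the predictor table,
#' and everything else the pipeline closes over, stays fixed. The p-value
#' uses the add-one formula `p = (1 + #\{null >= observed\}) / (1 + n)`, so
#' it is never exactly zero; with 50 permutations the minimum attainable
#' p is 1/51.
#'
#' @param pipeline function taking a response vector and returning a single
#'   numeric statistic, with larger meaning better. It should include every
#'   data-driven choice of the real analysis (variable selection, component
#'   selection, ...), so the null is honest.
#' @param response the observed response (labels or numeric targets).
#' @param nPermutations number of shuffles (default 50).
#' @param seed integer seed for the shuffles.
#' @param maxRetries a pipeline failure on a permuted response is retried
#'   with a freshly derived seed at most this many times before erroring.
#' @return List of class `permutationResult`: `observed`, `null` (numeric
#'   vector), `pValue`, `nPermutations`, `seed`, `failures` (count of
#'   retried iterations).
#' @export
permutationTest <- function(pipeline, response, nPermutations = 50L,
                            seed = 1L, maxRetries = 3L) {
  if (nPermutations < 1L)
    stop("'nPermutations' must be at least 1")
  observed <- pipeline(response)
  n <- length(response)
  nullStats <- numeric(nPermutations)
  failures <- 0L
  for (i in seq_len(nPermutations)) {
    attempt <- 0L
    repeat {
      permSeed <- as.integer(seed) + i + attempt * 100003L
      perm <- withSeed(permSeed, sample.int(n))
      res <- tryCatch(pipeline(response[perm]), error = identity)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      failures <- failures + 1L
      if (attempt > maxRetries)
        stop("pipeline failed on permutation ", i, " after ", maxRetries,
             " retries: ", conditionMessage(res))
    }
    nullStats[i] <- res
  }
  structure(list(observed = observed, null = nullStats,
                 pValue = (1 + sum(nullStats >= observed)) /
                   (1 + nPermutations),
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed), failures = failures),
            class = "permutationResult")
}

#' @export
print.permutationResult <- function(x, ...) {
  cat("permutationResult: observed ", format(x$observed), ", null mean ",
      format(mean(x$null)), " (", x$nPermutations, " permutations), p = ",
      format(x$pValue), "\n", sep = "")
  invisible(x)
}

## Tier metric bundle for classification: accuracy + weighted AUC on a
## probability matrix with true labels.
classificationTierMetrics <- function(prob, labels) {
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  auc <- weightedMulticlassAUC(prob, labels)
  list(accuracy = accuracy(labels, pred),
       weightedAUC = auc$weighted, perClassAUC = auc$perClass)
}
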