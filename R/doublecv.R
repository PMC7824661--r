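#' Iterative double cross-validation ensemble classification
#'
#' The outer split (built beforehand, e.g. with [stratifiedSplit()]) holds
#' the external test set aside. Within the outer training set, the inner
#' loop repeats `nIterations` times (default 50): a stratified 70/30 split
#' yields an inner training and an internal test set; a stratified k-fold
#' cross-validation on the inner training set produces out-of-fold CV
#' probabilities; a refit on the full inner training set predicts the
#' internal test and external test samples. Per tier, each sample's final
#' probability vector is the mean over the iterations that predicted it
#' out of training, and class membership is the arg-max of that mean.
#'
#' @param table a [BucketTable-class], or a numeric samples-by-variables
#'   matrix with sample ids as rownames.
#' @param labels class labels named by sample id (covering all ids in
#'   `plan`).
#' @param cfg a [doubleCVConfig()].
#' @param plan an outer `splitPlan` over the same ids.
#' @return List of class `doubleCVResult`:
#'   \describe{
#'     \item{meanProb}{per tier (`cv`, `internalTest`, `externalTest`), the
#'       matrix of mean class probabilities (rows named by sample id).}
#'     \item{counts}{per tier, the number of iterations contributing to
#'       each sample's mean.}
#'     \item{predictions}{per tier, the arg-max class labels.}
#'     \item{metrics}{per tier, accuracy / weighted AUC of the mean
#'       probabilities (the primary reading) plus `perIteration`, the mean
#'       over iterations of the per-iteration metrics (the alternative
#'       reading, logged for comparison).}
#'     \item{plans, cfg, outerPlan}{the full audit trail.}
#'   }
#' @export
runDoubleCV <- function(table, labels, cfg = doubleCVConfig(), plan) {
  X <- if (is(table, "BucketTable")) bucketMatrix(table) else as.matrix(table)
  allIds <- c(plan$trainIds, plan$testIds)
  if (!all(allIds %in% rownames(X)))
    stop("table rows do not cover all ids in the split plan")
  labels <- stats::setNames(as.character(labels[allIds]), allIds)
  classes <- sort(unique(labels))
  plans <- makeInnerPlans(plan, labels, cfg)
  nCls <- length(classes)
  acc <- function(ids) list(
    sum = matrix(0, length(ids), nCls, dimnames = list(ids, classes)),
    n = stats::setNames(integer(length(ids)), ids))
  tiers <- list(cv = acc(plan$trainIds),
                internalTest = acc(plan$trainIds),
                externalTest = acc(plan$testIds))
  perIter <- list(cv = list(), internalTest = list(), externalTest = list())
  add <- function(tier, prob) {
    ids <- rownames(prob)
    tiers[[tier]]$sum[ids, colnames(prob)] <<-
      tiers[[tier]]$sum[ids, colnames(prob)] + prob
    tiers[[tier]]$n[ids] <<- tiers[[tier]]$n[ids] + 1L
  }
  for (ip in plans) {
    itLab <- paste0("iteration ", ip$iteration)
    inTr <- ip$innerTrainIds
    cvProb <- matrix(NA_real_, length(inTr), nCls,
                     dimnames = list(inTr, classes))
    for (f in sort(unique(ip$foldAssignment))) {
      hold <- inTr[ip$foldAssignment[inTr] == f]
      if (!length(hold)) next
      keep <- setdiff(inTr, hold)
      model <- tryCatch(
        fitBaseLearner(X[keep, , drop = FALSE], labels[keep],
                       spec = cfg$learner, seed = ip$seed * 10L + f),
        error = function(e) stop(itLab, ", fold ", f, ": ",
                                 conditionMessage(e), call. = FALSE))
      p <- predictProb(model, X[hold, , drop = FALSE])
      cvProb[hold, colnames(p)] <- p
    }
    add("cv", cvProb)
    full <- tryCatch(
      fitBaseLearner(X[inTr, , drop = FALSE], labels[inTr],
                     spec = cfg$learner, seed = ip$seed),
      error = function(e) stop(itLab, ": ", conditionMessage(e),
                               call. = FALSE))
    intProb <- predictProb(full, X[ip$innerTestIds, , drop = FALSE])
    extProb <- predictProb(full, X[plan$testIds, , drop = FALSE])
    add("internalTest", intProb)
    add("externalTest", extProb)
    perIter$cv[[ip$iteration]] <-
      classificationTierMetrics(cvProb, labels[inTr])
    perIter$internalTest[[ip$iteration]] <-
      classificationTierMetrics(intProb, labels[ip$innerTestIds])
    perIter$externalTest[[ip$iteration]] <-
      classificationTierMetrics(extProb, labels[plan$testIds])
  }
  out <- list(meanProb = list(), counts = list(), predictions = list(),
              metrics = list(), plans = plans, cfg = cfg, outerPlan = plan,
              classes = classes)
  for (tn in names(tiers)) {
    n <- tiers[[tn]]$n
    covered <- names(n)[n > 0L]
    prob <- tiers[[tn]]$sum[covered, , drop = FALSE] / n[covered]
    out$meanProb[[tn]] <- prob
    out$counts[[tn]] <- n
    out$predictions[[tn]] <-
      stats::setNames(classes[max.col(prob, ties.method = "first")], covered)
    m <- classificationTierMetrics(prob, labels[covered])
    m$perIteration <- list(
      accuracy = mean(vapply(perIter[[tn]], `[[`, numeric(1), "accuracy")),
      weightedAUC = mean(vapply(perIter[[tn]], `[[`, numeric(1),
                                "weightedAUC")))
    out$metrics[[tn]] <- m
  }
  structure(out, class = "doubleCVResult")
}

#' @export
print.doubleCVResult <- function(x, ...) {
  cat("doubleCVResult: ", length(x$plans), " iteration(s), classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  for (tn in names(x$metrics))
    cat(sprintf("  %-13s accuracy = %.3f  weighted AUC = %.3f\n", tn,
                x$metrics[[tn]]$accuracy, x$metrics[[tn]]$weightedAUC))
  invisible(x)
}
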