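#' Probabilistic base-learner specification
#'
#' The double-CV workflow is agnostic to the classifier behind it: anything
#' that can be fit on a numeric matrix and return a class-probability
#' matrix qualifies. The default is gradient-boosted decision trees
#' (xgboost, `multi:softprob`), the learner used for the wine-variety
#' models. Custom learners plug in through `fitFun`.
#'
#' @param name learner name; `"xgboost"` selects the built-in backend.
#' @param nrounds,maxDepth,eta boosting rounds, tree depth and learning
#'   rate for the xgboost backend.
#' @param params extra xgboost parameters merged into the parameter list.
#' @param fitFun optional custom backend: `function(X, y, seed)` returning
#'   an object for which [predictProb()] has a method (or a list with a
#'   `predictProb` function element).
#' @return List of class `learnerSpec`.
#' @export
learnerSpec <- function(name = "xgboost", nrounds = 200L, maxDepth = 4L,
                        eta = 0.1, params = list(), fitFun = NULL) {
  structure(list(name = name, nrounds = as.integer(nrounds),
                 maxDepth = as.integer(maxDepth), eta = eta,
                 params = params, fitFun = fitFun),
            class = "learnerSpec")
}

#' Fit the base learner
#'
#' @param X numeric matrix (samples x variables).
#' @param y class labels (factor or character); at least two classes must
#'   be present.
#' @param spec a [learnerSpec()].
#' @param seed integer seed; with the xgboost backend (single thread,
#'   seeded) refits are bit-identical.
#' @return An object of class `baseLearner` supporting [predictProb()].
#' @export
fitBaseLearner <- function(X, y, spec = learnerSpec(), seed = 1L) {
  y <- as.factor(as.character(y))
  levs <- levels(y)
  if (length(levs) < 2L)
    stop("base learner needs at least two classes in 'y'")
  if (!is.null(spec$fitFun)) {
    model <- spec$fitFun(X, y, seed)
    return(structure(list(backend = "custom", model = model, levels = levs),
                     class = "baseLearner"))
  }
  if (!identical(spec$name, "xgboost"))
    stop("unknown learner '", spec$name, "' and no 'fitFun' supplied")
  params <- utils::modifyList(
    list(objective = "multi:softprob", num_class = length(levs),
         max_depth = spec$maxDepth, eta = spec$eta,
         nthread = 1L, seed = as.integer(seed)),
    spec$params)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                 label = as.integer(y) - 1L)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = spec$nrounds, verbose = 0)
  structure(list(backend = "xgboost", model = booster, levels = levs),
            class = "baseLearner")
}

#' Class-probability predictions from a fitted base learner
#'
#' @param model a `baseLearner` from [fitBaseLearner()].
#' @param X numeric matrix of new samples.
#' @return Matrix (samples x classes) of probabilities, columns named by
#'   class, rows summing to 1.
#' @export
predictProb <- function(model, X) {
  stopifnot(inherits(model, "baseLearner"))
  X <- as.matrix(X)
  prob <- switch(model$backend,
    xgboost = {
      p <- stats::predict(model$model, xgboost::xgb.DMatrix(X))
      matrix(p, nrow = nrow(X), ncol = length(model$levels), byrow = FALSE)
    },
    custom = {
      f <- model$model
      if (is.list(f) && is.function(f$predictProb)) f$predictProb(X)
      else stop("custom learner must expose a 'predictProb' function")
    })
  prob <- as.matrix(prob)
  if (ncol(prob) != length(model$levels))
    stop("probability matrix has wrong number of classes")
  prob <- prob / rowSums(prob)   # exact simplex (float32 backends drift)
  colnames(prob) <- model$levels
  rownames(prob) <- rownames(X)
  prob
}
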