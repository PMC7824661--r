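#' Single-response PLS model (NIPALS)
#'
#' Partial least squares regression for one numeric response, fitted by the
#' NIPALS deflation scheme on column-centred predictors and a centred
#' response. Latent variables are linear combinations of the predictors
#' built to covary with the response. For component a:
#' `w_a = X'y / ||X'y||`, `t_a = X w_a`, `p_a = X' t_a / (t_a' t_a)`,
#' `q_a = y' t_a / (t_a' t_a)`, then `X <- X - t_a p_a'` and
#' `y <- y - q_a t_a`. The coefficient vector on the original (centred)
#' variables is `b_k = W_k (P_k' W_k)^{-1} q_k`; at `k = rank(X)` the fit
#' coincides with ordinary least squares.
#'
#' @slot xMean per-variable centring offsets.
#' @slot yMean response mean.
#' @slot W,P weight and loading matrices (variables x components).
#' @slot q numeric response loadings, one per component.
#' @slot Tscores training score matrix (samples x components); columns are
#'   mutually orthogonal.
#' @slot coefPath matrix (variables x components); column k holds the
#'   coefficient vector of the k-component model.
#' @slot k chosen/effective number of components.
#'
#' @seealso [fitPLS()], [predictPLS()], [rmsecvCurve()],
#'   [selectComponents()]
#' @export
setClass("PLSFit",
         representation(xMean = "numeric", yMean = "numeric",
                        W = "matrix", P = "matrix", q = "numeric",
                        Tscores = "matrix", coefPath = "matrix",
                        k = "integer"))

setValidity("PLSFit", function(object) {
  msg <- character()
  Tm <- object@Tscores
  if (ncol(Tm) >= 2L) {
    g <- crossprod(Tm)
    rel <- abs(g[upper.tri(g)]) /
      sqrt(outer(diag(g), diag(g))[upper.tri(g)])
    if (any(rel > 1e-6))
      msg <- c(msg, "score columns are not mutually orthogonal")
  }
  if (object@k != ncol(Tm))
    msg <- c(msg, "'k' must equal the number of score columns")
  if (length(msg)) msg else TRUE
})

#' Fit a single-response PLS model
#'
#' @param X numeric predictor matrix (samples x variables).
#' @param y numeric response vector.
#' @param k requested number of latent variables; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`. If the deflated predictors run out of
#'   variance earlier, the model is truncated with a warning.
#' @return A [PLSFit-class].
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' f <- fitPLS(X, X[, 1] * 3, k = 1)
#' nComponents(f)
#' @export
fitPLS <- function(X, y, k) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2L)
  if (stats::var(y) == 0) stop("constant response: PLS undefined")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1")
  if (k > min(n - 1L, p))
    stop("'k' = ", k, " exceeds min(n - 1, p) = ", min(n - 1L, p))
  xMean <- colMeans(X); yMean <- mean(y)
  Xc <- sweep(X, 2, xMean); yc <- y - yMean
  sc0 <- sum(Xc^2)
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Tm <- matrix(0, n, k); q <- numeric(k)
  eff <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sc0))) break
    w <- w / nw
    t <- as.numeric(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12 * max(1, sc0)) break
    pv <- as.numeric(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    eff <- a
  }
  if (eff == 0L) stop("predictors carry no covariance with the response")
  if (eff < k)
    warning("rank exhausted after ", eff, " of ", k,
            " requested components; model truncated")
  W <- W[, seq_len(eff), drop = FALSE]
  P <- P[, seq_len(eff), drop = FALSE]
  Tm <- Tm[, seq_len(eff), drop = FALSE]
  q <- q[seq_len(eff)]
  coefPath <- matrix(0, p, eff)
  for (kk in seq_len(eff)) {
    Wk <- W[, seq_len(kk), drop = FALSE]
    Pk <- P[, seq_len(kk), drop = FALSE]
    coefPath[, kk] <- Wk %*% solve(crossprod(Pk, Wk), q[seq_len(kk)])
  }
  rownames(coefPath) <- colnames(X)
  new("PLSFit", xMean = xMean, yMean = yMean, W = W, P = P, q = q,
      Tscores = Tm, coefPath = coefPath, k = eff)
}

#' @rdname nComponents
#' @export
setMethod("nComponents", "PLSFit", function(x) x@k)

#' @rdname scores
#' @export
setMethod("scores", "PLSFit", function(x) x@Tscores)

#' @rdname regressionCoefficients
#' @export
setMethod("regressionCoefficients", "PLSFit",
          function(x, k = nComponents(x)) x@coefPath[, k])

setMethod("show", "PLSFit", function(object) {
  cat("PLSFit: ", ncol(object@coefPath), " latent variable(s) on ",
      length(object@xMean), " variable(s), ", nrow(object@Tscores),
      " training sample(s)\n", sep = "")
})

#' Predict from a PLS model
#'
#' `yhat = yMean + (Xnew - xMean) b_k`. With `k = 0` the prediction is the
#' training response mean (null model).
#'
#' @param fit a [PLSFit-class].
#' @param Xnew matrix with the same variables as the training data.
#' @param k number of components to use (default: the fitted count).
#' @return Numeric predictions, one per row of `Xnew`.
#' @export
predictPLS <- function(fit, Xnew, k = nComponents(fit)) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(fit@xMean))
    stop("'Xnew' has ", ncol(Xnew), " variable(s) but the model was fit on ",
         length(fit@xMean))
  k <- as.integer(k)
  if (k < 0L || k > nComponents(fit))
    stop("'k' must be between 0 and ", nComponents(fit))
  if (k == 0L) return(rep(fit@yMean, nrow(Xnew)))
  fit@yMean + as.numeric(sweep(Xnew, 2, fit@xMean) %*% fit@coefPath[, k])
}

#' RMSECV curve over component counts
#'
#' Repeated randomized k-fold cross-validation: for each iteration a fresh
#' random fold assignment is drawn (fold sizes within one of each other),
#' each fold is predicted by a model fit on the remaining folds at every
#' component count, and `RMSECV(k)` is the root of the squared errors
#' pooled over all folds and iterations.
#'
#' @param X,y training data.
#' @param kMax largest component count to evaluate (default 20); silently
#'   truncated, with a warning, when the smallest training fold cannot
#'   support it.
#' @param folds folds per iteration (default 5).
#' @param nIterations randomized repetitions (default 20).
#' @param seed integer seed; iteration i uses `seed + i`.
#' @return List of class `rmsecvCurve` with `k`, `rmsecv`, `folds`,
#'   `nIterations`, `seed`.
#' @export
rmsecvCurve <- function(X, y, kMax = 20L, folds = 5L, nIterations = 20L,
                        seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds) stop("need at least as many samples as folds")
  minTrain <- n - ceiling(n / folds)
  kEff <- min(as.integer(kMax), minTrain - 1L, ncol(X))
  if (kEff < as.integer(kMax))
    warning("component count truncated to ", kEff,
            " by training-fold size/rank")
  if (kEff < 1L) stop("training folds too small for even one component")
  sse <- numeric(kEff); nPred <- 0L
  for (it in seq_len(nIterations)) {
    fold <- withSeed(as.integer(seed) + it,
                     rep_len(seq_len(folds), n)[sample.int(n)])
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- suppressWarnings(fitPLS(X[tr, , drop = FALSE], y[tr],
                                     k = min(kEff, sum(tr) - 1L)))
      for (kk in seq_len(kEff)) {
        pred <- predictPLS(fit, X[!tr, , drop = FALSE],
                           k = min(kk, nComponents(fit)))
        sse[kk] <- sse[kk] + sum((y[!tr] - pred)^2)
      }
      nPred <- nPred + sum(!tr)
    }
  }
  structure(list(k = seq_len(kEff), rmsecv = sqrt(sse / nPred),
                 folds = as.integer(folds),
                 nIterations = as.integer(nIterations),
                 seed = as.integer(seed)),
            class = "rmsecvCurve")
}

#' @export
print.rmsecvCurve <- function(x, ...) {
  cat("rmsecvCurve: k = 1..", max(x$k), ", min RMSECV ",
      format(min(x$rmsecv)), " at k = ", which.min(x$rmsecv), "\n", sep = "")
  invisible(x)
}

#' Choose the number of PLS components from an RMSECV curve
#'
#' Scanning upward from one component, component k+1 is accepted while
#' `RMSECV(k+1) <= (1 - improvement) * RMSECV(k)`; the scan stops at the
#' first k whose successor fails the test. When the successor rises this is
#' the first local minimum of the curve; otherwise it is the point where
#' the relative improvement first drops below the threshold (default 2%).
#' Exactly equal successive values count as no improvement.
#'
#' @param curve an [rmsecvCurve()] result, or a bare numeric RMSECV vector
#'   indexed by component count.
#' @param improvement minimum relative decrease to accept another
#'   component (default 0.02).
#' @param kMax hard cap on the returned count (default 20).
#' @return Chosen component count (integer).
#' @examples
#' selectComponents(c(5, 3, 4, 2))      # 2
#' selectComponents(c(10, 5, 4.9, 6))   # 3
#' selectComponents(c(10, 9.9, 9.8))    # 1
#' @export
selectComponents <- function(curve, improvement = 0.02, kMax = 20L) {
  r <- if (inherits(curve, "rmsecvCurve")) curve$rmsecv else as.numeric(curve)
  if (!length(r)) stop("empty RMSECV curve")
  kTop <- min(length(r), as.integer(kMax))
  k <- 1L
  while (k < kTop && r[k + 1L] <= (1 - improvement) * r[k])
    k <- k + 1L
  k
}

#' Score-space outlier detection (Hotelling T-squared)
#'
#' Formalizes the 95% confidence ellipse on the scatterplot of the first
#' two latent variables: with centred scores `t_1, t_2` and their variances
#' `s_a^2`, `T2_i = sum_a t_ia^2 / s_a^2`, and sample i is excluded when
#' `T2_i > 2 (n - 1) / (n - 2) * F_conf(2, n - 2)`.
#'
#' @param scoreMatrix numeric matrix whose first two columns are the
#'   latent-variable scores (e.g. `scores(fit)`).
#' @param confidence ellipse coverage (default 0.95).
#' @param ids sample ids; default rownames or indices.
#' @return List of class `outlierReport`: `excludedIds`, `t2` (named),
#'   `threshold`, `confidence`. Degenerate (zero-variance) scores yield a
#'   warning and no exclusions.
#' @export
detectOutliers <- function(scoreMatrix, confidence = 0.95, ids = NULL) {
  sc <- as.matrix(scoreMatrix)[, 1:2, drop = FALSE]
  n <- nrow(sc)
  if (n < 4L) stop("outlier detection needs at least 4 samples")
  if (is.null(ids))
    ids <- if (!is.null(rownames(sc))) rownames(sc)
           else as.character(seq_len(n))
  sc <- sweep(sc, 2, colMeans(sc))
  s2 <- apply(sc, 2, stats::var)
  if (any(s2 <= .Machine$double.eps)) {
    warning("degenerate scores (zero variance); no outliers flagged")
    return(structure(list(excludedIds = character(0),
                          t2 = stats::setNames(rep(0, n), ids),
                          threshold = Inf, confidence = confidence),
                     class = "outlierReport"))
  }
  t2 <- sc[, 1]^2 / s2[1] + sc[, 2]^2 / s2[2]
  names(t2) <- ids
  threshold <- 2 * (n - 1) / (n - 2) * stats::qf(confidence, 2, n - 2)
  structure(list(excludedIds = ids[t2 > threshold], t2 = t2,
                 threshold = threshold, confidence = confidence),
            class = "outlierReport")
}

#' @export
print.outlierReport <- function(x, ...) {
  cat("outlierReport: ", length(x$excludedIds), " of ", length(x$t2),
      " sample(s) outside the ", 100 * x$confidence,
      "% ellipse (T2 > ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' Tiered evaluation of a PLS regression model
#'
#' Computes R-squared and RMSE for calibration (RMSEC), cross-validation
#' (RMSECV at the chosen component count) and the external test set
#' (RMSEP). Calibration R-squared is taken about the training mean; the CV
#' and external tiers also use the training mean as reference, so a
#' predictor no better than that mean scores at or below zero. Squared
#' Pearson correlations are logged alongside, the convention being
#' otherwise a matter of taste.
#'
#' @param fit a fitted [PLSFit-class].
#' @param XTrain,yTrain calibration data (as used for the fit).
#' @param XTest,yTest external test data; `NULL` omits the tier with a
#'   warning.
#' @param curve optional [rmsecvCurve()] used for the CV tier.
#' @param k component count in use (default: the fit's).
#' @param permutation optional `permutationResult` whose p-value is echoed.
#' @return List of class `regressionEvalReport` with `tiers` (named lists
#'   holding `r2`, `rmse`, `r2Corr`), `k`, `nVariables`, `permutationP`.
#' @export
evaluateRegression <- function(fit, XTrain, yTrain, XTest = NULL,
                               yTest = NULL, curve = NULL,
                               k = nComponents(fit), permutation = NULL) {
  trainMean <- mean(yTrain)
  predTrain <- predictPLS(fit, XTrain, k = k)
  tiers <- list(calibration = list(
    r2 = rSquared(yTrain, predTrain, trainMean),
    rmse = rmse(yTrain, predTrain),
    r2Corr = suppressWarnings(stats::cor(yTrain, predTrain))^2))
  if (!is.null(curve)) {
    rc <- curve$rmsecv[min(k, max(curve$k))]
    tiers$cv <- list(
      r2 = 1 - rc^2 / mean((yTrain - trainMean)^2),
      rmse = rc, r2Corr = NA_real_)
  }
  if (is.null(XTest) || is.null(yTest) || length(yTest) == 0L) {
    warning("no external test samples; external tier omitted")
  } else {
    predTest <- predictPLS(fit, XTest, k = k)
    tiers$external <- list(
      r2 = rSquared(yTest, predTest, trainMean),
      rmse = rmse(yTest, predTest),
      r2Corr = suppressWarnings(stats::cor(yTest, predTest))^2)
  }
  structure(list(tiers = tiers, k = as.integer(k),
                 nVariables = length(fit@xMean),
                 permutationP = if (!is.null(permutation))
                   permutation$pValue else NA_real_),
            class = "regressionEvalReport")
}

#' @export
print.regressionEvalReport <- function(x, ...) {
  cat("regressionEvalReport (k = ", x$k, ", ", x$nVariables,
      " variable(s)):\n", sep = "")
  for (tn in names(x$tiers))
    cat(sprintf("  %-12s R2 = %.4f  RMSE = %.5g\n", tn,
                x$tiers[[tn]]$r2, x$tiers[[tn]]$rmse))
  if (!is.na(x$permutationP))
    cat("  permutation p = ", format(x$permutationP), "\n", sep = "")
  invisible(x)
}
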