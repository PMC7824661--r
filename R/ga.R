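#' Genetic-algorithm configuration for variable selection
#'
#' @param populationSize even number of chromosomes (default 64).
#' @param nGenerations generations to evolve (default 100).
#' @param crossoverRate probability a parent pair undergoes uniform
#'   crossover (default 0.5).
#' @param mutationRate per-bit flip probability (default 0.005).
#' @param elitismCount chromosomes copied unchanged each generation
#'   (default 2).
#' @param initInclusionProb probability a variable starts selected
#'   (default 0.3).
#' @param fitness one of `"cv-rmse"` (regression; higher fitness =
#'   negative RMSECV), `"cv-accuracy"` or `"cv-weighted-auc"`
#'   (classification).
#' @param seed integer seed.
#' @return List of class `gaConfig`.
#' @export
gaConfig <- function(populationSize = 64L, nGenerations = 100L,
                     crossoverRate = 0.5, mutationRate = 0.005,
                     elitismCount = 2L, initInclusionProb = 0.3,
                     fitness = c("cv-rmse", "cv-accuracy",
                                 "cv-weighted-auc"),
                     seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(populationSize %% 2L == 0L, populationSize >= 2L,
            elitismCount < populationSize,
            crossoverRate >= 0, crossoverRate <= 1,
            mutationRate >= 0, mutationRate <= 1,
            initInclusionProb > 0, initInclusionProb <= 1,
            nGenerations >= 1L)
  structure(list(populationSize = as.integer(populationSize),
                 nGenerations = as.integer(nGenerations),
                 crossoverRate = crossoverRate,
                 mutationRate = mutationRate,
                 elitismCount = as.integer(elitismCount),
                 initInclusionProb = initInclusionProb,
                 fitness = fitness, seed = as.integer(seed)),
            class = "gaConfig")
}

#' Cross-validated fitness of a variable mask
#'
#' Regression (`"cv-rmse"`): negative RMSECV of a PLS model on the masked
#' variables at the component count chosen by [selectComponents()] (capped
#' at 10 inside the GA for speed), using the frozen fold plan. Classification
#' (`"cv-accuracy"`, `"cv-weighted-auc"`): the base learner is fit per fold
#' and the out-of-fold probabilities pooled; the named metric is returned.
#' Higher is always better. The fold plan is frozen per GA run so fitness
#' is a deterministic function of the mask.
#'
#' @param mask logical vector over the table columns; at least one `TRUE`.
#' @param X samples-by-variables matrix.
#' @param response labels (classification) or numeric targets (regression).
#' @param fitness fitness name as in [gaConfig()].
#' @param foldPlan integer fold labels, one per sample.
#' @param learner a [learnerSpec()] (classification only).
#' @param maxComponents PLS component cap (regression only, default 10).
#' @param seed seed forwarded to the base learner.
#' @return Scalar fitness, higher = better.
#' @export
fitnessEval <- function(mask, X, response, fitness, foldPlan,
                        learner = learnerSpec(), maxComponents = 10L,
                        seed = 1L) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask selects no variables")
  Xm <- X[, mask, drop = FALSE]
  folds <- sort(unique(foldPlan))
  if (fitness == "cv-rmse") {
    y <- as.numeric(response)
    minTrain <- min(vapply(folds, function(f) sum(foldPlan != f),
                           integer(1)))
    kTop <- max(1L, min(as.integer(maxComponents), ncol(Xm),
                        minTrain - 1L))
    sqErr <- matrix(NA_real_, nrow(Xm), kTop)
    for (f in folds) {
      tr <- foldPlan != f
      fit <- suppressWarnings(fitPLS(Xm[tr, , drop = FALSE], y[tr],
                                     k = min(kTop, sum(tr) - 1L,
                                             ncol(Xm))))
      for (kk in seq_len(kTop)) {
        p <- predictPLS(fit, Xm[!tr, , drop = FALSE],
                        k = min(kk, nComponents(fit)))
        sqErr[!tr, kk] <- (y[!tr] - p)^2
      }
    }
    curve <- sqrt(colMeans(sqErr))
    kSel <- selectComponents(curve, kMax = kTop)
    -curve[kSel]
  } else {
    lab <- as.character(response)
    classes <- sort(unique(lab))
    prob <- matrix(NA_real_, nrow(Xm), length(classes),
                   dimnames = list(NULL, classes))
    for (f in folds) {
      tr <- foldPlan != f
      model <- fitBaseLearner(Xm[tr, , drop = FALSE], lab[tr],
                              spec = learner, seed = seed)
      p <- predictProb(model, Xm[!tr, , drop = FALSE])
      prob[!tr, colnames(p)] <- p
    }
    if (fitness == "cv-accuracy") {
      pred <- classes[max.col(prob, ties.method = "first")]
      accuracy(lab, pred)
    } else {
      weightedMulticlassAUC(prob, lab)$weighted
    }
  }
}

#' Genetic-algorithm variable selection
#'
#' Binary-encoded chromosomes over the table columns; tournament selection
#' (size 2), uniform crossover, per-bit mutation, elitism. A chromosome
#' mutated to all-zero is repaired by activating one random bit. Fitness is
#' [fitnessEval()] under a fold plan frozen at the start of the run, and
#' fitness values are cached per chromosome, so the best-ever fitness
#' trajectory is nondecreasing.
#'
#' Selection is meant to run once, on the outer training set only, before
#' double-CV or final PLS fitting, so the external test never influences
#' which variables survive.
#'
#' @param table a [BucketTable-class] or samples-by-variables matrix.
#' @param response labels or numeric targets (must match `cfg$fitness`).
#' @param cfg a [gaConfig()].
#' @param learner a [learnerSpec()] used by classification fitness.
#' @param foldsN folds in the frozen fitness plan (default 5).
#' @return List of class `gaResult`: `mask` (logical, best-ever),
#'   `fitness` (its fitness), `trajectory` (best-ever fitness per
#'   generation), `nSelected`, `cfg`.
#' @export
runGA <- function(table, response, cfg = gaConfig(),
                  learner = learnerSpec(), foldsN = 5L) {
  X <- if (is(table, "BucketTable")) bucketMatrix(table) else as.matrix(table)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty variable table")
  p <- ncol(X)
  classification <- cfg$fitness != "cv-rmse"
  foldPlan <- if (classification)
    stratifiedFolds(as.character(response), foldsN, seed = cfg$seed)
  else withSeed(cfg$seed, rep_len(seq_len(foldsN), nrow(X))[sample.int(nrow(X))])
  cache <- new.env(parent = emptyenv())
  evalMask <- function(mask) {
    key <- rawToChar(as.raw(45L + mask))
    got <- get0(key, cache)
    if (!is.null(got)) return(got)
    val <- fitnessEval(mask, X, response, cfg$fitness, foldPlan,
                       learner = learner, seed = cfg$seed)
    assign(key, val, cache)
    val
  }
  withSeed(cfg$seed, {
    pop <- matrix(stats::runif(cfg$populationSize * p) <
                    cfg$initInclusionProb,
                  nrow = cfg$populationSize)
    for (i in seq_len(cfg$populationSize))
      if (!any(pop[i, ])) pop[i, sample.int(p, 1L)] <- TRUE
    fit <- apply(pop, 1, evalMask)
    bestIdx <- which.max(fit)
    best <- list(mask = pop[bestIdx, ], fitness = fit[bestIdx],
                 generation = 0L)
    trajectory <- numeric(cfg$nGenerations)
    for (g in seq_len(cfg$nGenerations)) {
      elite <- order(-fit)[seq_len(cfg$elitismCount)]
      children <- matrix(FALSE, cfg$populationSize, p)
      nChild <- cfg$populationSize - cfg$elitismCount
      ci <- 0L
      while (ci < nChild) {
        pick <- function() {
          cand <- sample.int(cfg$populationSize, 2L)
          cand[which.max(fit[cand])]
        }
        a <- pop[pick(), ]; b <- pop[pick(), ]
        if (stats::runif(1) < cfg$crossoverRate) {
          swap <- stats::runif(p) < 0.5
          tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        }
        for (child in list(a, b)) {
          if (ci >= nChild) break
          flip <- stats::runif(p) < cfg$mutationRate
          child <- xor(child, flip)
          if (!any(child)) child[sample.int(p, 1L)] <- TRUE
          ci <- ci + 1L
          children[ci, ] <- child
        }
      }
      pop <- rbind(pop[elite, , drop = FALSE],
                   children[seq_len(nChild), , drop = FALSE])
      fit <- apply(pop, 1, evalMask)
      gi <- which.max(fit)
      if (fit[gi] > best$fitness)
        best <- list(mask = pop[gi, ], fitness = fit[gi], generation = g)
      trajectory[g] <- best$fitness
    }
    structure(list(mask = best$mask, fitness = best$fitness,
                   trajectory = trajectory,
                   nSelected = sum(best$mask),
                   generationFound = best$generation, cfg = cfg),
              class = "gaResult")
  })
}

#' @export
print.gaResult <- function(x, ...) {
  cat("gaResult: ", x$nSelected, " of ", length(x$mask),
      " variable(s) selected; best fitness ", format(x$fitness),
      " (generation ", x$generationFound, " of ",
      x$cfg$nGenerations, ")\n", sep = "")
  invisible(x)
}
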