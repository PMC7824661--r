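test_that("the base learner separates, hedges and reproduces", {
  X <- matrix(c(rnorm(20, -5, 0.2), rnorm(20, 5, 0.2)), ncol = 1)
  y <- rep(c("lo", "hi"), each = 20)
  m <- fitBaseLearner(X, y, spec = fastLearner(), seed = 1L)
  p <- predictProb(m, X)
  expect_equal(colnames(p), c("hi", "lo"))
  expect_equal(unname(rowSums(p)), rep(1, 40), tolerance = 1e-6)
  pred <- colnames(p)[max.col(p)]
  expect_equal(accuracy(y, pred), 1)

  # identical rows with conflicting labels: probabilities stay inside (0,1)
  Xc <- matrix(1, 20, 1)
  yc <- rep(c("a", "b"), 10)
  pc <- predictProb(fitBaseLearner(Xc, yc, spec = fastLearner(), seed = 1L),
                    Xc)
  expect_true(all(pc > 0 & pc < 1))

  # determinism contract
  set.seed(7); Xr <- matrix(rnorm(200), 40, 5)
  yr <- rep(c("a", "b"), 20)
  p1 <- predictProb(fitBaseLearner(Xr, yr, spec = fastLearner(), seed = 3L), Xr)
  p2 <- predictProb(fitBaseLearner(Xr, yr, spec = fastLearner(), seed = 3L), Xr)
  expect_identical(p1, p2)

  expect_error(fitBaseLearner(Xr, rep("a", 40)), "two classes")
})

test_that("custom learners plug in behind the probability contract", {
  centroid <- function(X, y, seed) {
    mus <- matrix(vapply(levels(y),
                         function(l) colMeans(X[y == l, , drop = FALSE]),
                         numeric(ncol(X))),
                  nrow = ncol(X))
    list(predictProb = function(Xn) {
      d <- vapply(seq_len(ncol(mus)), function(j)
        rowSums(sweep(Xn, 2, mus[, j])^2), numeric(nrow(Xn)))
      w <- exp(-d); w / rowSums(w)
    })
  }
  X <- matrix(c(rnorm(10, -2), rnorm(10, 2)), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  m <- fitBaseLearner(X, y, spec = learnerSpec(fitFun = centroid), seed = 1L)
  p <- predictProb(m, X)
  expect_equal(colnames(p), c("a", "b"))
  expect_gt(accuracy(y, colnames(p)[max.col(p)]), 0.9)
})

makeSmallRun <- function(nIterations, masterSeed, nPerClass = 8L) {
  cfg <- smallSimConfig(nPerClass = nPerClass, seed = 2L)
  ds <- simulateClassificationSet(cfg)
  bt <- bucketTable(ds$spectra)
  labels <- namedLabels(ds)
  plan <- stratifiedSplit(labels, 0.8, seed = 1L)
  dcv <- runDoubleCV(bt, labels,
                     doubleCVConfig(nIterations = nIterations,
                                    learner = fastLearner(30L),
                                    masterSeed = masterSeed),
                     plan)
  list(dcv = dcv, labels = labels, plan = plan)
}

test_that("double CV never leaks external samples and conserves probability", {
  run <- makeSmallRun(3L, masterSeed = 1L)
  ext <- run$plan$testIds
  for (ip in run$dcv$plans) {
    expect_length(intersect(ext, ip$innerTrainIds), 0L)
    expect_length(intersect(ext, ip$innerTestIds), 0L)
    expect_setequal(c(ip$innerTrainIds, ip$innerTestIds), run$plan$trainIds)
  }
  for (tier in names(run$dcv$meanProb)) {
    sums <- rowSums(run$dcv$meanProb[[tier]])
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
  # every external sample is predicted by every iteration
  expect_true(all(run$dcv$counts$externalTest == 3L))
  # internal-test counts only reflect iterations where the sample was held out
  innerCounts <- sapply(run$plan$trainIds, function(id)
    sum(vapply(run$dcv$plans, function(ip) id %in% ip$innerTestIds,
               logical(1))))
  expect_equal(unname(run$dcv$counts$internalTest[run$plan$trainIds]),
               unname(innerCounts))
})

test_that("two iterations equal the composition of two single-iteration runs", {
  run2 <- makeSmallRun(2L, masterSeed = 5L)
  runA <- makeSmallRun(1L, masterSeed = 5L)  # iteration seed 6
  runB <- makeSmallRun(1L, masterSeed = 6L)  # iteration seed 7
  for (tier in c("cv", "internalTest", "externalTest")) {
    sumA <- runA$dcv$meanProb[[tier]] * 0
    nA <- runA$dcv$counts[[tier]]; nB <- runB$dcv$counts[[tier]]
    ids <- names(run2$dcv$counts[[tier]])
    combined <- matrix(0, length(ids), 3,
                       dimnames = list(ids, colnames(run2$dcv$meanProb[[tier]])))
    cnt <- setNames(numeric(length(ids)), ids)
    for (r in list(runA, runB)) {
      pr <- r$dcv$meanProb[[tier]]; n <- r$dcv$counts[[tier]]
      covered <- rownames(pr)
      combined[covered, ] <- combined[covered, ] +
        pr * n[covered]
      cnt[covered] <- cnt[covered] + n[covered]
    }
    keep <- cnt > 0
    expect_equal(combined[keep, ] / cnt[keep],
                 run2$dcv$meanProb[[tier]][names(cnt)[keep], ],
                 tolerance = 1e-12)
  }
})

test_that("ensemble accuracy degrades as class separation shrinks", {
  sepLevels <- c(2.5, 0.75, 0)
  acc <- sapply(sepLevels, function(sep) {
    mean(vapply(1:8, function(seed) {
      base <- rep_len(c(5, 3, 8, 2, 6, 4, 7, 3), 8)
      cm <- matrix(rep(base, each = 3), nrow = 3)
      cm[2, c(1, 4)] <- cm[2, c(1, 4)] + sep
      cm[3, c(2, 6)] <- cm[3, c(2, 6)] + sep
      cfg <- smallSimConfig(nPerClass = 12L, seed = seed, classMeans = cm)
      ds <- simulateClassificationSet(cfg)
      labels <- namedLabels(ds)
      plan <- stratifiedSplit(labels, 0.8, seed = seed)
      dcv <- runDoubleCV(bucketTable(ds$spectra), labels,
                         doubleCVConfig(nIterations = 3L,
                                        learner = fastLearner(30L),
                                        masterSeed = seed),
                         plan)
      dcv$metrics$externalTest$accuracy
    }, numeric(1)))
  })
  expect_true(all(diff(acc) < 0))
})
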