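test_that("a single component fits an exactly one-dimensional relation", {
  set.seed(1)
  X <- cbind(x1 = rnorm(20), x2 = 0, x3 = 0)
  X[, 2:3] <- 1e-14 * matrix(rnorm(40), 20, 2)  # avoid exact zero columns
  y <- 3 * X[, 1]
  fit <- fitPLS(X, y, k = 1)
  expect_equal(predictPLS(fit, X), y, tolerance = 1e-8)
  expect_equal(rSquared(y, predictPLS(fit, X)), 1, tolerance = 1e-10)
})

test_that("PLS at full rank equals ordinary least squares", {
  set.seed(1)
  for (i in 1:5) {
    X <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    fit <- fitPLS(X, y, k = 4)
    ols <- unname(predict(lm(y ~ X)))
    expect_equal(predictPLS(fit, X), ols, tolerance = 1e-8)
    # and on new data
    Xn <- matrix(rnorm(20), 5, 4)
    olsNew <- unname(cbind(1, Xn) %*% coef(lm(y ~ X)))[, 1]
    expect_equal(predictPLS(fit, Xn), olsNew, tolerance = 1e-8)
  }
})

test_that("predictions respect centering, k = 0 and affine shifts", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, 4)
  y <- X[, 1] - 2 * X[, 3] + rnorm(15, 0, 0.1)
  fit <- fitPLS(X, y, k = 3)
  expect_equal(predictPLS(fit, X, k = 0), rep(mean(y), 15))
  expect_equal(predictPLS(fit, matrix(fit@xMean, 1)), mean(y),
               tolerance = 1e-10)
  # adding a constant to one variable in train and new data changes nothing
  X2 <- X; X2[, 2] <- X2[, 2] + 5
  fit2 <- fitPLS(X2, y, k = 3)
  Xnew <- matrix(rnorm(20), 5, 4)
  Xnew2 <- Xnew; Xnew2[, 2] <- Xnew2[, 2] + 5
  expect_equal(predictPLS(fit2, Xnew2), predictPLS(fit, Xnew),
               tolerance = 1e-8)
  expect_error(predictPLS(fit, Xnew[, 1:3]), "variable")
  expect_error(fitPLS(X, y, k = 20), "exceeds")
  expect_error(fitPLS(X, rep(1, 15), k = 2), "constant response")
})

test_that("scores are orthogonal and the coefficient path matches sequential reconstruction", {
  set.seed(3)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  fit <- fitPLS(X, y, k = 6)
  Tm <- scores(fit)
  g <- crossprod(Tm)
  offdiag <- abs(g[upper.tri(g)]) / sqrt(outer(diag(g), diag(g))[upper.tri(g)])
  expect_true(all(offdiag < 1e-8))
  # prediction via b equals the accumulated t_a * q_a reconstruction
  for (k in c(1, 3, 6)) {
    viaScores <- fit@yMean +
      as.numeric(Tm[, 1:k, drop = FALSE] %*% fit@q[1:k])
    viaCoef <- predictPLS(fit, X, k = k)
    expect_equal(viaCoef, viaScores, tolerance = 1e-8)
  }
})

test_that("the RMSECV curve is deterministic and flattens at the true rank", {
  set.seed(4)
  Tlat <- matrix(rnorm(80), 40, 2)
  P <- matrix(rnorm(12), 6, 2)
  X <- Tlat %*% t(P)
  y <- Tlat %*% c(1, -2)
  c1 <- suppressWarnings(rmsecvCurve(X, y, kMax = 5, seed = 9L))
  c2 <- suppressWarnings(rmsecvCurve(X, y, kMax = 5, seed = 9L))
  expect_identical(c1, c2)
  expect_lt(c1$rmsecv[2] / c1$rmsecv[1], 0.01)
  expect_true(all(c1$rmsecv[2:length(c1$rmsecv)] < 1e-6 * c1$rmsecv[1]))
  expect_equal(selectComponents(c1), 2L)
})

test_that("pure-noise responses show no spurious cross-validated gains", {
  set.seed(5)
  wins <- 0L; total <- 0L
  kSel <- integer(10)
  for (seed in 1:10) {
    X <- matrix(rnorm(40 * 10), 40, 10)
    y <- rnorm(40)
    cv <- suppressWarnings(rmsecvCurve(X, y, kMax = 8, nIterations = 5,
                                       seed = seed))
    wins <- wins + sum(cv$rmsecv[-1] >= cv$rmsecv[1])
    total <- total + length(cv$rmsecv) - 1L
    kSel[seed] <- selectComponents(cv)
  }
  expect_gt(wins / total, 0.6)
  expect_lte(median(kSel), 2)
})

test_that("component selection follows the local-minimum / 2% rule exactly", {
  expect_equal(selectComponents(c(5, 3, 4, 2)), 2L)
  expect_equal(selectComponents(c(10, 5, 4.9, 6)), 3L)
  expect_equal(selectComponents(c(10, 9.9, 9.8)), 1L)
  # ties are non-improvements
  expect_equal(selectComponents(c(5, 5, 1)), 1L)
  # kMax caps a monotone chain
  expect_equal(selectComponents(seq(100, 10, length.out = 30), kMax = 20), 20L)
  expect_error(selectComponents(numeric(0)), "empty")
})

test_that("Hotelling exclusion flags a planted outlier and calibrates near 5%", {
  set.seed(1)
  sc <- cbind(rnorm(100), rnorm(100))
  sc <- rbind(sc, c(10, 10))
  rep <- detectOutliers(sc, ids = as.character(1:101))
  expect_identical(rep$excludedIds, "101")

  expect_warning(out <- detectOutliers(matrix(1, 10, 2)), "degenerate")
  expect_length(out$excludedIds, 0L)
  expect_error(detectOutliers(matrix(rnorm(6), 3, 2)), "at least 4")

  set.seed(2)
  big <- cbind(rnorm(2000), rnorm(2000, sd = 3))
  rate <- length(detectOutliers(big)$excludedIds) / 2000
  expect_lt(abs(rate - 0.05), 0.015)
})

test_that("tiered evaluation reports calibration, CV and external metrics", {
  set.seed(6)
  X <- matrix(rnorm(50 * 6), 50, 6)
  beta <- c(1, -1, 2, 0, 0, 0.5)
  y <- as.numeric(X %*% beta) + rnorm(50, 0, 0.05)
  tr <- 1:40; te <- 41:50
  curve <- suppressWarnings(rmsecvCurve(X[tr, ], y[tr], kMax = 6, seed = 1L))
  k <- selectComponents(curve)
  fit <- fitPLS(X[tr, ], y[tr], k = k)
  ev <- evaluateRegression(fit, X[tr, ], y[tr], X[te, ], y[te],
                           curve = curve, k = k)
  expect_named(ev$tiers, c("calibration", "cv", "external"))
  expect_gt(ev$tiers$external$r2, 0.9)
  expect_gte(ev$tiers$calibration$r2, ev$tiers$cv$r2)
  expect_warning(evaluateRegression(fit, X[tr, ], y[tr]), "omitted")
  # a mean-only predictor cannot beat R2 = 0 on test data
  fit0 <- fitPLS(X[tr, ], y[tr], k = 1)
  pred0 <- rep(mean(y[tr]), length(te))
  expect_lte(rSquared(y[te], pred0, referenceMean = mean(y[tr])), 0)
})

test_that("NIPALS predictions agree with the mixOmics reference implementation", {
  suppressMessages(library(mixOmics))
  set.seed(3)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(paste0("s", 1:30), paste0("v", 1:6)))
  y <- as.numeric(X %*% c(1, -2, 0, 0.5, 0, 0) + rnorm(30, 0, 0.2))
  fit <- fitPLS(X, y, k = 3)
  ref <- mixOmics::pls(X, matrix(y, dimnames = list(rownames(X), "y")),
                       ncomp = 3, mode = "regression", scale = FALSE)
  Xn <- matrix(rnorm(30), 5, 6,
               dimnames = list(paste0("n", 1:5), colnames(X)))
  for (k in 1:3)
    expect_equal(predictPLS(fit, Xn, k = k),
                 unname(predict(ref, Xn)$predict[, , k]), tolerance = 1e-10)
})

test_that("external prediction error recovers the generative target noise", {
  rmseps <- vapply(1:5, function(seed) {
    cfg <- smallSimConfig(nPerClass = 50L, seed = seed,
                          targetNoiseSd = 0.3)
    ds <- simulateRegressionSet(cfg)
    bt <- bucketTable(ds$spectra)
    targets <- setNames(ds$targets, sampleIds(ds))
    rep <- runRegressionWorkflow(bt, targets, nTest = 15L, kMax = 10L,
                                 cvIterations = 5L, seed = seed)
    rep$eval$tiers$external$rmse
  }, numeric(1))
  pooled <- sqrt(mean(rmseps^2))
  expect_lt(abs(pooled - 0.3) / 0.3, 0.25)
})
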