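test_that("the default bucket grid has 950 positions, 860 after exclusion", {
  spec <- bucketSpec()
  # independent enumeration of the inclusive arithmetic grid
  enumerated <- round(seq(0.50, 9.99, by = 0.01), 10)
  expect_length(enumerated, 950L)
  retainedOracle <- enumerated
  for (i in seq_len(nrow(solventExclusions()))) {
    win <- solventExclusions()[i, ]
    retainedOracle <- retainedOracle[!(retainedOracle >= win[1] - 1e-9 &
                                         retainedOracle <= win[2] + 1e-9)]
  }
  pos <- bucketPositions(spec)
  expect_length(pos, 860L)
  expect_equal(pos, retainedOracle, tolerance = 1e-9)
  # per-window drop counts: 38 + 43 + 9
  expect_equal(950L - 860L, 90L)

  tiny <- bucketSpec(lo = 1.0, hi = 1.05, width = 0.01, exclusions = NULL)
  expect_equal(bucketPositions(tiny), seq(1.00, 1.05, by = 0.01),
               tolerance = 1e-9)
})

test_that("no retained position falls inside an exclusion window", {
  pos <- bucketPositions(bucketSpec())
  ex <- solventExclusions()
  for (i in seq_len(nrow(ex)))
    expect_false(any(pos >= ex[i, 1] - 1e-9 & pos <= ex[i, 2] + 1e-9))
})

test_that("bucket spec validity catches malformed inputs", {
  expect_error(bucketSpec(lo = 2, hi = 1), "lo")
  expect_error(bucketSpec(width = 0), "width")
  expect_error(bucketSpec(exclusions = matrix(c(1, 2, 1.5, 3), 2, 2,
                                              byrow = TRUE)),
               "overlap")
  expect_error(bucketSpec(exclusions = matrix(c(0.1, 0.6), 1, 2)),
               "within")
})

test_that("total-intensity normalization scales, is idempotent and scale-invariant", {
  spec <- bucketSpec(lo = 1, hi = 2, width = 0.01, exclusions = NULL)
  n <- 101L
  s <- nmrSpectrum("flat", seq(1, 2, length.out = n), rep(4.2, n))
  ns <- normalizeTotalIntensity(s, spec)
  expect_equal(intensity(ns), rep(1 / n, n))
  expect_equal(intensity(normalizeTotalIntensity(ns, spec)), intensity(ns),
               tolerance = 1e-12)

  cfg <- smallSimConfig(nPerClass = 1L, seed = 1L)
  sp <- simulateClassificationSet(cfg)$spectra[[1]]
  scaled <- nmrSpectrum(sampleId(sp), chemicalShift(sp),
                        7.3 * intensity(sp))
  expect_equal(intensity(normalizeTotalIntensity(sp, bucketSpec())),
               intensity(normalizeTotalIntensity(scaled, bucketSpec())),
               tolerance = 1e-12)

  bad <- nmrSpectrum("neg", seq(1, 2, length.out = 11), rep(-1, 11))
  expect_error(normalizeTotalIntensity(bad, spec), "neg")
})

test_that("bucketSpectrum assigns point masses and honours exclusions", {
  spec <- bucketSpec(lo = 1, hi = 1.1, width = 0.01,
                     exclusions = matrix(c(1.03, 1.05), 1, 2))
  grid <- seq(0.995, 1.105, by = 0.001)
  y <- numeric(length(grid))
  y[which.min(abs(grid - 1.061))] <- 5   # inside bucket 1.06
  s <- nmrSpectrum("pm", grid, y)
  v <- bucketSpectrum(s, spec)
  expect_equal(sum(v), 5)
  expect_equal(unname(v[names(v) == "1.06"]), 5)

  y2 <- numeric(length(grid))
  y2[grid >= 1.03 & grid <= 1.049] <- 1  # all mass in the exclusion zone
  v2 <- bucketSpectrum(nmrSpectrum("ex", grid, y2), spec)
  expect_true(all(v2 == 0))

  short <- nmrSpectrum("short", seq(1.02, 1.1, by = 0.001),
                       rep(1, length(seq(1.02, 1.1, by = 0.001))))
  expect_error(bucketSpectrum(short, spec), "missing span")
})

test_that("bucketSpectrum matches the brute-force reassignment oracle", {
  # generated noiseless spectrum on the default grid and spec
  cfg <- wineSimConfig(noiseSd = 0)
  s <- simulateSpectrum(cfg, c(5, 3, 8, 2, 6, 4, 7, 3), seed = 1L)
  s <- normalizeTotalIntensity(s, bucketSpec())
  expect_equal(unname(bucketSpectrum(s, bucketSpec())),
               unname(bucketOracle(s, bucketSpec())), tolerance = 1e-12)

  # 50 random spectra on random small specs
  set.seed(42)
  for (i in 1:50) {
    spec <- bucketSpec(lo = 1, hi = 1.5, width = 0.01,
                       exclusions = matrix(c(1.2, 1.3), 1, 2))
    grid <- sort(runif(300, 0.99, 1.51))
    grid <- grid[c(TRUE, diff(grid) > 0)]
    s <- nmrSpectrum(paste0("r", i), grid, rnorm(length(grid)))
    expect_equal(unname(bucketSpectrum(s, spec)),
                 unname(bucketOracle(s, spec)), tolerance = 1e-12)
  }
})

test_that("bucket vectors conserve the normalized total outside exclusion zones", {
  spec <- bucketSpec()
  grid <- seq(0.5, 9.99, by = 0.005)
  ex <- solventExclusions()
  # zero out every point ASSIGNED to an excluded bucket, i.e. the windows
  # widened by half a bucket (the partition-consistent exclusion zone)
  w <- 0.01
  inEx <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(ex)))
    inEx <- inEx | (grid >= ex[i, 1] - w / 2 - w * 1e-6 &
                      grid < ex[i, 2] + w / 2 - w * 1e-6)
  set.seed(9)
  y <- abs(rnorm(length(grid))) + 0.01
  y[inEx] <- 0
  s <- normalizeTotalIntensity(nmrSpectrum("cons", grid, y), spec)
  expect_equal(sum(bucketSpectrum(s, spec)), 1, tolerance = 1e-9)
})

test_that("bucket tables assemble, permute and round-trip", {
  cfg <- smallSimConfig(nPerClass = 2L, seed = 2L)
  ds <- simulateClassificationSet(cfg)
  bt <- bucketTable(ds$spectra)
  m <- bucketMatrix(bt)
  expect_equal(dim(m), c(6L, 860L))
  expect_identical(rownames(m), sampleIds(ds))
  expect_equal(bucketPositions(bt), bucketPositions(bucketSpec()))

  # permuting input order permutes rows only
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  m2 <- bucketMatrix(bucketTable(ds$spectra[perm]))
  expect_equal(m2, m[perm, ])

  expect_error(bucketTable(ds$spectra[c(1, 1)]), "duplicate")

  empty <- bucketTable(list())
  expect_equal(dim(bucketMatrix(empty)), c(0L, 860L))

  f <- tempfile(fileext = ".csv")
  writeBucketTableCSV(bt, f)
  rt <- readBucketTableCSV(f)
  expect_equal(unname(rt$matrix), unname(m), tolerance = 1e-12)
  expect_equal(rt$ppm, bucketPositions(bt), tolerance = 1e-9)
  unlink(f)
})

test_that("spectrum CSV IO preserves content and detects headers", {
  s <- nmrSpectrum("io", seq(1, 2, by = 0.01), rnorm(101))
  f <- tempfile(fileext = ".csv")
  writeSpectrumCSV(s, f)
  # written descending; reader restores ascending order
  r <- readSpectrumCSV(f)
  expect_equal(chemicalShift(r), chemicalShift(s))
  expect_equal(intensity(r), intensity(s), tolerance = 1e-12)
  # headerless variant
  writeLines(apply(cbind(chemicalShift(s), intensity(s)), 1, paste,
                   collapse = ","), f)
  r2 <- readSpectrumCSV(f, sampleId = "io")
  expect_equal(intensity(r2), intensity(s), tolerance = 1e-6)
  unlink(f)
})
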