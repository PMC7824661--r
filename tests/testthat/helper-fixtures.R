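# Shared fixtures: scaled-down simulation configs and a light learner so
# unit tests stay fast; the full-size study conditions live in
# test-acceptance.R.

# Coarser ppm grid (0.002 ppm) halves the point count; still 5 raw points
# per 0.01-ppm bucket.
smallSimConfig <- function(nPerClass = 10L, seed = 1L, ...) {
  wineSimConfig(ppmStep = 0.002, nPerClass = nPerClass, seed = seed, ...)
}

fastLearner <- function(nrounds = 50L) learnerSpec(nrounds = nrounds)

sampleIds <- function(ds) vapply(ds$spectra, sampleId, character(1))

namedLabels <- function(ds) {
  stats::setNames(as.character(ds$labels), sampleIds(ds))
}

# Brute-force per-bucket reassignment oracle: for every retained bucket
# position, scan all grid points and sum those falling in its half-open
# window (final bucket closed on the right). Edges use the same
# exact-edge-goes-right convention as the implementation, via a 1e-6
# bucket-width tolerance.
bucketOracle <- function(s, spec) {
  pos <- bucketPositions(spec)
  ppm <- chemicalShift(s); y <- intensity(s)
  w <- spec@width
  hi <- spec@hi
  tol <- w * 1e-6
  vapply(pos, function(p) {
    inb <- ppm >= p - w / 2 - tol & ppm < p + w / 2 - tol
    if (abs(p - hi) < tol)
      inb <- inb | abs(ppm - (hi + w / 2)) <= tol
    sum(y[inb])
  }, numeric(1))
}

# Pairwise-counting AUC oracle (ties = 1/2).
aucPairOracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
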