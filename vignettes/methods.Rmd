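---
title: "Models, conventions and design decisions in vinometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design decisions in vinometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vinometrics` models wine composition and variety from bucketed 1D ¹H NMR
spectra. This vignette records the science behind each stage and, where
the underlying conventions were genuinely open, the choice the package
makes and why. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Preprocessing: normalization and bucketing

A processed spectrum arrives as a (δ, intensity) series on a fine grid
(ppm). Two operations reduce it to the modeling table.

**Total-intensity normalization.** All intensities are scaled by one
constant so the sum over grid points in δ 0.50–9.99 ppm equals 1. This
removes dilution and receiver-gain differences while preserving relative
peak areas. Two conventions are defensible for the denominator: including
or excluding the solvent windows that are later discarded. The package
normalizes over the *full* range by default — normalization is described
before exclusion in the standard workflow, and the ethanol/water signal
dominates a wine spectrum, so this choice materially affects the scale of
the retained variables — and exposes `excludeSolvent = TRUE` on
`normalizeTotalIntensity()`/`bucketTable()` for the post-exclusion
alternative. Noise-induced negative intensities are kept as-is; no floor
is applied.

**Bucket grid.** Buckets are *positions* `0.50, 0.51, …, 9.99` (width
0.01 ppm, inclusive ends): 950 positions. A position is dropped iff it
lies inside an exclusion window, endpoints included:

| window | positions dropped |
|---|---|
| δ 0.98–1.35 (ethanol) | 38 |
| δ 3.43–3.85 (ethanol) | 43 |
| δ 4.78–4.86 (water)   | 9 |

leaving **860 retained variables**. This position-based, closed-endpoint
counting is the only convention that produces 860 from these windows; it
is therefore fixed as normative.

**Point assignment.** A grid point δ belongs to the bucket position p
with `p − w/2 ≤ δ < p + w/2` — half-open windows partition the axis
without double counting; the final bucket is closed on the right. Bucket
values are plain sums of grid-point intensities: on a uniform grid the
trapezoidal integral differs only by a constant factor that the
normalization cancels. Grid points falling exactly on a window edge are
resolved by a 10⁻⁶-bucket-width nudge toward the upper bucket, so the
assignment is stable against floating-point representation of the edges
(relevant because typical acquisition grids place points exactly on
half-bucket boundaries). Positions themselves are constructed by integer
indexing (`lo + width * 0:n`), never by accumulating floats.

A practical consequence of partition semantics: "zero intensity in the
exclusion zones" means zero over the excluded *buckets'* windows (the
nominal intervals widened by half a bucket); only then is the retained
bucket sum exactly the normalized total.

The spectrum must cover [lo, hi]; the half-bucket overhangs at either end
contribute when present but are not required, since a grid starting
exactly at 0.5 ppm is the common case.

## 2. Iterative double cross-validation classification

The classification workflow estimates generalization without letting
model selection touch the test data:

1. **Outer split** — stratified 80/20. The total training size is
   ⌊0.8·n⌋ and per-class counts follow largest-remainder rounding of the
   per-class quotas. This rounding is deliberate: for three-class sets of
   128 and 122 samples it yields 102/26 and 97/25, whereas naive
   rounding would give 98 on the second (97.6 → 98). Remainder ties break
   by class order.
2. **Inner loop** — 50 iterations. Iteration *i* is seeded
   `masterSeed + i` (simple, reproducible, auditable) and draws a
   stratified 70/30 split of the outer training set; the 70 % gets a
   stratified 5-fold assignment (within each class, shuffle and deal
   round-robin, so per-class fold sizes differ by ≤ 1).
3. **Predictions** — per iteration: out-of-fold CV probabilities for the
   70 %, and a refit on the full 70 % predicts the 30 % internal test and
   the external set.
4. **Ensembling** — a sample's tier probability is the mean over
   iterations that predicted it *out of training*: internal-test means
   use only iterations where the sample fell in the 30 % (≈ 15 of 50);
   external means use all 50. Only out-of-training predictions are
   honest, so in-training iterations never contribute.

Tier metrics (accuracy, count-weighted one-vs-rest AUC) are computed on
these averaged probabilities — the primary reading. The mean of
per-iteration metrics is also logged (`metrics$<tier>$perIteration`),
since with single reported values per tier either aggregation is
defensible; the two agree closely whenever the ensemble is stable.

**Base learner.** Gradient-boosted trees (xgboost, `multi:softprob`,
single-threaded and seeded so refits are bit-identical). Defaults:
500 → **200 rounds**, depth 4, learning rate 0.1. Two hundred rounds at
η = 0.1 is converged on tables of this size (hundreds of samples × 860
buckets), and the 50-model ensemble supplies additional variance
reduction; the heavier 500-round setting buys nothing measurable at twice
the cost. All hyperparameters are exposed via `learnerSpec()`, and any
probabilistic classifier can be plugged in through `fitFun`. Probability
rows from float32 backends are renormalized to sum exactly to 1.

Structural invariants — external ids never appearing in any training
fold, CV predictions coming only from models that excluded the sample's
fold — are asserted in the test suite over the full set of plans.

## 3. PLS regression

`fitPLS()` implements single-response NIPALS exactly as written in the
class documentation; SIMPLS would give identical predictions for one
response but NIPALS is the form directly verifiable against the deflation
equations, and at `k = rank(X)` the fit provably coincides with ordinary
least squares (tested against `lm()`, and against mixOmics as an
independent reference).

**Component choice.** A repeated randomized 5-fold RMSECV curve
(20 iterations, components capped at 20) feeds the sequential rule:
accept component k+1 while `RMSECV(k+1) ≤ 0.98 · RMSECV(k)`, stop at the
first failure. When the next value rises this stop *is* the first local
minimum; otherwise it is the ≥ 2 % improvement cutoff. Exactly equal
successive values count as non-improvement (a tie is no evidence for the
extra component). Squared errors are pooled over all folds × iterations
before the single root — pooling is the lower-variance estimator of the
CV error — and per-fold RMSEs are recoverable from the curve object's
seeds if wanted.

**Outlier exclusion.** The "95 % confidence region on the score plot of
the first two latent variables" is formalized as Hotelling T² with
per-component score variances: `T²ᵢ = t²ᵢ₁/s₁² + t²ᵢ₂/s₂²` against
`2(n−1)/(n−2) · F₀.₉₅(2, n−2)` (scores are uncorrelated by construction,
so the diagonal form is the full T²). Exclusion runs **once**, on a
preliminary 2-component fit, before component selection; the refit on the
cleaned data is automatic. Running it before selection keeps the RMSECV
curve itself free of leverage points; the order was otherwise open.
Degenerate (zero-variance) scores yield a warning and no exclusions. On
clean bivariate-normal scores the empirical exclusion rate calibrates to
≈ 5 % (asserted at n = 2000 within ±1.5 points).

**Reporting conventions.** R² = 1 − SSE/SST with SST about the training
mean in every tier (for calibration that is the tier's own mean), so a
predictor no better than the training mean scores ≤ 0 on test data.
Squared Pearson correlations are logged alongside since the alternative
convention is common. The CV tier's R² derives from the pooled RMSECV at
the chosen k.

External test sets are chronological — the last `nTest` samples in
acquisition order — mirroring how a deployed model faces genuinely newer
samples.

## 4. Genetic-algorithm variable selection

No standard exists for GA mechanics in this setting, so the package fixes
conventional literature defaults, all exposed in `gaConfig()`: population
64, 100 generations, tournament selection (size 2), uniform crossover at
rate 0.5, per-bit mutation 0.005, elitism 2, initial inclusion
probability 0.3. Fitness is the cross-validated quality of the downstream
model restricted to the mask — negative RMSECV at the selected component
count (capped at 10 inside the GA, for speed) for regression; pooled
out-of-fold weighted AUC of the base learner for classification. The fold
plan is frozen per run so fitness is a deterministic function of the
mask, fitness values are cached per chromosome, and elitism makes the
best-ever trajectory nondecreasing. All-zero chromosomes are repaired by
activating one random bit. Selection runs **once, on the outer training
set only**, before the double-CV loop or final PLS fit — re-selecting
inside every iteration would be defensible but a single selection per
model matches reporting one final variable count, and the external set
must never influence which variables survive.

## 5. Permutation validation

`permutationTest()` shuffles the *response* (Y-scrambling) while the
spectra stay fixed — for model-significance purposes this is the standard
chemometric randomization and equivalent in null content to scrambling
the rows of X. The full pipeline, including variable selection and
component selection, is re-run per permutation by default; a
`permutationFreezeMask` switch reuses the observed GA mask (much faster,
anti-conservative, and warned about accordingly). The p-value uses the
add-one formula `p = (1 + #{null ≥ observed})/(1 + n)`, so with the
default 50 permutations the minimum attainable p is 1/51 ≈ 0.0196 and p
is never zero. A failed permutation refit is retried with a derived seed
(at most 3 times) rather than silently dropped.

## 6. The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth; it emulates the *structure* of wine NMR data, not its
chemistry:

* Lorentzian peaks (the natural NMR line shape; pseudo-Voigt adds a shape
  parameter with no testing benefit and is deliberately omitted) on a
  δ 0.5–10.0 grid at 0.001-ppm steps — 10 raw points per bucket, enough
  for the integration tests.
* Eight abstract "metabolites" spread over δ 0.9–9.3, placed outside the
  exclusion windows so their signal survives bucketing; base
  concentration means 2–8 (a.u.) with SD 0.5, HWHM 0.008 ppm.
* Three classes; the defaults shift two metabolites per non-reference
  class by +2.5 = 5 SD — a cleanly recoverable scenario. Null scenarios
  use identical means; intermediate separations are used in the
  difficulty-monotonicity test.
* Concentrations are Gaussian truncated at zero by redraw, preserving
  physical nonnegativity without materially distorting means at SD/mean
  ≤ 0.25.
* Solvent artifacts: three large Lorentzians (amplitudes 40–100, i.e. an
  order of magnitude above the metabolites, as ethanol/water dominate
  real wine spectra) centred in the excluded windows.
* Additive Gaussian noise, default SD 0.05 against peak heights of
  ~100–300.
* Quantitative targets are linear in the concentrations
  (`target = β·conc + ε`), loading on four of the eight metabolites, with
  noise SD 0.1 by default.

What the generator does **not** emulate — J-coupling multiplets, phase
and baseline distortion, peak-position drift between samples, the TSP
reference peak, field-strength effects — bounds what passing tests show:
they validate the statistical machinery (splitting, ensembling,
selection, calibration) and the bucketing arithmetic, not robustness to
instrumental artifacts. On real spectra, alignment quality and baseline
handling will matter in ways no test here exercises.

## 7. Problem sizes, tolerances and degenerate inputs

* Recovery runs use the study-sized conditions: 120 samples (3 × 40) for
  classification with the full 50-iteration loop, 150 samples for
  regression with the full 20-iteration RMSECV. Unit tests use smaller
  instances (coarser 0.002-ppm grids, 3–10 iterations, 30–60-round
  learners) chosen to exercise the same code paths quickly.
* Oracle equivalences (PLS vs OLS, bucketing vs brute-force
  reassignment, rank-based vs pair-counting AUC) are asserted at 1e-8 or
  tighter; determinism contracts at bit identity.
* Rank-deficient PLS requests truncate with a warning rather than error;
  a response with zero variance errors.
* `stratifiedSplit()` refuses classes with fewer than 2 members;
  `makeInnerPlans()` refuses outer training sets whose smallest class
  cannot sustain the fold count, naming the class.
* Seeds are plain integers; every derived seed stays far below 2³¹.

## 8. Known limitations

* The ensemble reports no probability calibration; averaged
  gradient-boosting probabilities are ranking-faithful (AUC) but not
  calibrated frequencies.
* One spectrum per sample; replicate handling is out of scope.
* The GA is single-objective; parsimony enters only through CV fitness,
  so selected-variable counts are data- and setting-dependent.
* Multi-target (PLS2) regression, orthogonal-PLS variants and prediction
  intervals are out of scope.
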