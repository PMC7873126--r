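---
title: "Cleaning untargeted LC-MS feature tables with pooled-QC anchoring"
author: "lcmsqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning untargeted LC-MS feature tables with pooled-QC anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsqc)
```

## The problem

Untargeted LC-MS profiling of a multi-species field experiment produces a
feature table — thousands of (m/z, retention time) features by hundreds of
injections — that cannot be analysed as exported. Three properties get in the
way:

* **Sparsity.** Each plant species detects only its own metabolite
  fingerprint, so a table spanning thirteen grassland species is ~90% empty.
  Empty cells mix true biological absences with technical dropouts.
* **Batch structure.** Hundreds of injections are measured in analytical
  batches separated by source cleaning and recalibration. Feature intensities
  shift multiplicatively between batches, and in the uncorrected data this
  batch signal dominates the leading principal components.
* **Artefacts.** Procedural contaminants (visible in blank injections),
  uninformative elution windows (injection front, column wash), and the
  occasional mislabelled or contaminated sample.

`lcmsqc` implements the corresponding cleaning pipeline over the
Workflow4Metabolomics (W4M) triplet format — `dataMatrix`, `sampleMetadata`,
`variableMetadata` — in a fixed stage order:

1. retention-time region-of-interest (ROI) filter,
2. noise imputation of missing cells,
3. batch correction anchored on repeated pooled-QC injections,
4. removal of the QC injections,
5. blank-based contaminant filtering,
6. species fingerprint construction,
7. per-sample validity check (Mahalanobis distance + shared fingerprint).

A synthetic-data generator reproduces the statistical structure of the study
design the pipeline targets, so every stage is testable without downloading
anything.

## The study design model

The design encoded by `study_design()` is a factorial field sampling: two
pools of eight species (four grasses, four herbs; three species sit in both
pools, giving 13 distinct species), four seasonal time points, four plot
diversity levels (1, 2, 4, 8 sown species), two replicates — 4 × 4 × 2 × 8 ×
2 = 512 study samples. One documented loss (a sample tube broken before
analysis) leaves 511 analytical samples.

```{r design}
d <- study_design()
d
rec <- apply_known_losses(enumerate_study_samples(d))
nrow(rec)
```

Samples carry Lab-IDs (`NNN_YYYY_S`, numbers 001–128 per season) assigned
randomly at sampling time; extraction and injection follow Lab-ID order,
which is what randomizes species, diversity and replicate across batches.
`build_injection_sequence()` distributes the records over 12 batches of four
11-sample blocks in Lab-ID order (batches fill to 44; the shortfall from the
lost sample trails in the final batch, which holds 27), with a run-in (three
solvent injections and a pooled QC), a QC and one blank before the first
block, and a QC after every block. That layout yields six QC injections per
full batch. The number of QCs per batch is a consequence of the layout, not a
hard-coded constant, so designs with repeated or additional QC injections are
representable by changing the block structure.

## What the generator emulates — and what it does not

`simulate_study()` produces the full 594-column table (511 study + 71 QC +
12 blank injections) with known ground truth. Its default `sim_config()`
encodes the study conditions:

* **Fingerprints.** Each species owns 200 fingerprint features, 20 of which
  form a core shared by all species; 30 contaminant features belong to no
  fingerprint but appear everywhere, including blanks. Feature base
  intensities are log-normal: log10 intensity ~ N(3.2, 0.5), with a
  between-sample biological spread of 0.3 log10 units and a per-QC-injection
  technical spread of 0.05.
* **Detection.** A fingerprint feature is missed in a given sample with
  probability 0.35 (dropout), and any intensity below the detection threshold
  of 100 counts — the noise floor of the upstream peak detection — is
  censored to missing. With these defaults the full matrix lands within two
  percentage points of the 90% empty-cell fraction the targeted study
  reports.
* **Pooled-QC dilution.** QC columns are the mean of all study profiles
  before batch effects: a feature carried by one 32-sample species is diluted
  ~16-fold in the pool, so weak single-species features fall below the
  threshold in the QC. This reproduces the observation that the pooled QC
  detects only about half of all features. The QC detection mask is treated
  as a property of the pooled material — fixed across injections — because a
  pool is one homogeneous extract; letting the threshold flip per injection
  would inject a nonlinear batch effect that the linear correction model
  explicitly does not claim to remove.
* **Batch effects.** Feature-wise multiplicative effects, constant within a
  batch and additive on the log scale, spanned by a small number of random
  directions (default rank 3) with per-feature log10 sd 1.2. The magnitude is
  calibrated against the targeted study's own diagnostic: its uncorrected QC
  inter-batch distance ratio (~17) indicates batch shifts that dwarf
  technical noise, and at sd 1.2 the simulated ratio reaches the same order
  (around eleven in the README's worked run). Smaller values leave the
  simulated batch signal too close to the
  imputation-noise floor to reproduce the reported near-complete removal.
* **Outliers.** Optionally, study samples whose detected fingerprint is
  partially swapped for another species' features (default swap fraction
  0.8), emulating contaminated or mislabelled samples.

The generator does **not** emulate chromatographic peak shapes, m/z-level
isotope/adduct structure, injection-order drift within batches, correlated
metabolite modules, or season/diversity effects on the profiles. Passing
tests therefore demonstrate that the pipeline's operations are correct under
the declared statistical structure; they do not certify performance against
drift or correlated biology that the model omits.

## Imputation

Missing cells (zeros and NA markers alike) are replaced by |x| with
x ~ Normal(70, 20) (`impute_noise()`). The parameters sit below the
detection threshold of 100 so imputed noise remains distinguishable from
measured signal. Draws are deliberately *not* truncated at the threshold:
the distribution itself is the specification and ~6.7% of draws exceed 100
(Φ((100−70)/20) ≈ 0.933 below). The folding |·| matters only 3.5 sd from
zero and is statistically negligible, but it guarantees non-negative
intensities. The logical mask of imputed cells is carried on the resulting
table; every later stage that needs pre-imputation detection status (blank
filtering, fingerprints, shared-fraction checks, output variants) reads the
mask rather than guessing.

## Batch correction

`fit_batch_correction()` implements the pooled-QC flavour of removal of
unwanted variation: on the natural-log scale the QC profiles are centered by
their global mean and the top *k* right singular vectors of the centered QC
matrix become the unwanted-variation directions. `predict()` centers every
sample by the QC mean, subtracts the projection onto those directions, and
maps back to the intensity scale; QC samples are corrected alongside study
samples so post-correction diagnostics remain computable. Because the pooled
QC is a single replicate group, the replicate-centered SVD coincides with
the RUV unwanted-factor estimate, and least-squares residual regression on
those factors is algebraically the same orthogonal projection — which is why
the package exposes one implementation rather than a flag between two
identical computations.

**Distance diagnostic.** `batch_distances()` summarizes batch structure as
`intra` (mean distance of each log1p profile to its own batch centroid) and
`inter` (mean pairwise distance among batch centroids divided by `intra`).
The ratio is dimensionless as defined; per-feature unit-variance scaling is
available (`standardize = TRUE`) but off by default. With roughly half of the
QC cells imputed, unit scaling gives every imputed-noise feature the same
weight as a batch-dominated feature, which bounds the achievable
post-correction improvement near 60% no matter how large the true effect is —
the raw log scale lets batch-dominated features carry their actual weight.

**Choosing k.** `scree_select_k()` computes the QC inter-batch distance for
k = 0..k_max from a single SVD (the projections are nested) and picks the
smallest k whose decrease to k+1 falls below 1% *of the uncorrected
distance*. Measuring flatness against the k = 0 value rather than the
current value keeps the rule stable at the noise floor, where relative
decreases of an already-small distance never quite vanish. Two curve columns
are reported: the unnormalized centroid distance, which is exactly
non-increasing in k (nested projections), and the normalized ratio, which
may wiggle by ~0.1% past the elbow because the intra term also shrinks.

## Feature filters

* **ROI.** Features with retention time in [80 s, 840 s] are kept, bounds
  inclusive on both ends. The cut regions are the injection front / very
  polar window and the column-wash / very nonpolar window. The boundary
  intent of a "cut below 80, above 840" rule is ambiguous at exactly 80/840;
  the package keeps the boundary features and exposes the bounds.
* **Blank filter.** Any feature detected (pre-imputation) in at least one
  blank is removed everywhere, and the blanks are then dropped. The threshold
  is configurable (`min_blank_detections`) because a stricter
  25%-of-blanks counting rule is equally defensible for tables with many
  blank injections; the default follows the "at least one blank" reading,
  and neither rule is silently preferred — callers choose.
* **Fingerprints.** A feature belongs to a species when detected in at least
  `max(8, ceiling(0.25 · n))` of its n study samples. For the 32-sample
  species of the full design the two criteria coincide at 8; for the three
  dual-pool species (64 samples) the fraction rule dominates at 16, keeping
  "25% of the cohort" the governing idea with 8 as a floor.

## Sample validity

For each species, `mahalanobis_per_species()` computes distances to the
species centroid on the log scale. With far more features than samples the
sample covariance is singular; the default regularization estimates the
covariance in a PCA score space of `min(n − 2, 10)` dimensions (pseudo-
inverse and diagonal-shrinkage covariances are available). The centroid and
covariance use all samples of the species — only the peer average is
leave-one-out ("the remaining samples") — a deliberate stability choice:
re-estimating the covariance per left-out sample at n ≈ 32 buys noise, not
robustness. A sample passes when its distance is at most 3× the peer
average (strictly greater fails) *and* it shares strictly more than 25% of
its species fingerprint, the fingerprint being the denominator. Whether the
original analysis computed distances on raw, log or PCA-reduced data is not
recoverable from its description, so the package treats the published list
of excluded samples as qualitative context, not as a unit-test oracle; the
operating characteristics are instead validated on simulated outliers with
known ground truth (sensitivity 100%, false-positive rate ≤ 2% over 20
simulation seeds, zero failures under the null).

## Numerical and degenerate-input choices

* Zero-variance QC fits are flagged (`zero_variance`) rather than erroring;
  identical profiles report an inter-batch distance of 0 with the flag set.
* Distances treat `intra < 1e-12` as zero variance; scree selection treats a
  distance below 1e-12 as already-flat and stops.
* Logs: correction uses `log`/`exp` (requires the strictly positive imputed
  matrix, guarantees positive output); diagnostics use `log1p` so they are
  also computable on zero-convention tables; Mahalanobis uses `log` when the
  matrix is positive (making decisions exactly scale invariant) and `log1p`
  otherwise.
* All randomness flows through explicit integer seeds; the global RNG state
  of the caller is restored after every seeded operation.
* Intensities are stored as doubles; integers widen on read. NA markers
  serialize as the literal token `NA`; TSV is tab-separated UTF-8 with `.`
  decimals, matrix features-in-rows (transposed input is rejected, not
  guessed).

## Problem sizes used by the test suite

The suite exercises the full study scale throughout: 594-column simulated
tables (2390 features), 20-seed Monte-Carlo loops for the scree-recovery and
validity operating characteristics, 10^5 cells for the imputation
distribution checks, and n = 2000 samples for the chi-square expectation of
the regularized Mahalanobis distance. These sizes were chosen so that every
stochastic assertion has Monte-Carlo error well inside its tolerance.

## Known limitations

* The correction model is linear on the log scale; threshold-crossing
  (detection flips between batches) is a real phenomenon the model does not
  remove — in this package it is confined to study samples, where it is part
  of the biological detection process the fingerprint rule absorbs.
* Injection-order drift within batches (QC-RSC/LOESS territory) is out of
  scope, as are empirical-Bayes batch methods.
* The inter-batch distance is one of several defensible formulas; published
  numerical values computed with an unpublished formula cannot be matched
  exactly, only in pattern (QC ratio large before correction, near the study
  level after; study ratio essentially unchanged).
* Validation is per species on the corrected matrix; iterative re-validation
  after exclusions and robust covariance estimates (MCD) are not provided.
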