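---
title: "Methods: multi-block fusion of LC and FTIR fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-block fusion of LC and FTIR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chemfuse` classifies the geographic origin of natural-product samples from
two instrumental fingerprints per sample — an LC chromatogram (intensity vs
retention time) and an ATR-FTIR spectrum (absorbance vs wavenumber) — and
quantifies whether fusing the two blocks identifies origins that either
block alone confuses. This vignette is the package's own account of the
methods: what each stage computes, which tunable parameters matter, what
the synthetic data generator does and does not emulate, and where genuinely
open design choices were resolved.

## Pretreatment

**Retention-time correction (COW).** Chromatograms drift in retention time
between runs. `cow_align()` warps each sample onto a reference (the
column-wise mean of the calibration samples) by piecewise-linear warping:
the axis is divided into segments of `segment_length` points (default 50),
each internal segment boundary may move up to `slack` points (default 15)
from its reference position, and the boundary offsets are optimized jointly
per sample by exact dynamic programming maximizing the summed Pearson
correlation of warped segments with the reference segments. Two numerical
conventions matter:

- *Slack bounds the boundary offset itself*, not the increment between
  neighbours. This makes `segment_length >= 2*slack + 3` sufficient for
  monotone node maps, makes exhaustive enumeration feasible (the test suite
  verifies the dynamic program against brute force on every instance with
  up to 4 segments and slack up to 2), and recovers the ~5-point shifts the
  generator plants with the default 50/15 parameters.
- *Ties prefer the un-warped position.* In zero-variance segments every
  offset scores the same correlation (defined as 0 there); candidate
  predecessors are visited in the order 0, −1, +1, −2, … so that aligning
  the reference to itself returns the identity node map.

Defaults were chosen so a 7201-point, 60-min chromatogram with shifts of a
few points is recoverable; both are configurable per run.

**Data reduction and derivative filtering.** `downsample_every_k()` keeps
columns 1, 1+k, 1+2k, … (default k = 3: 7201 → 2401 points), starting at
the first point. `sg_second_derivative()` applies a Savitzky–Golay
second-derivative filter (second-order local polynomial, 15-point window)
along each row, which removes constant baseline offsets and linear drift
exactly and sharpens overlapped bands. The filter weights are computed by
local least squares with unit index spacing, and the `(window−1)/2` edge
columns on each side are *discarded*, not padded: 2401 → 2387 variables.
Truncation (rather than padding) is the convention that keeps the variable
count bookkeeping exact, and the derivative scale (per index, not per
axis unit) is irrelevant to classification because PLS-DA autoscales and
trees are scale-invariant.

**Band deletion.** `remove_bands()` drops every variable whose axis value
falls inside a closed interval; the FTIR chain deletes 1750–2670 and
3700–4000 cm⁻¹ (detector noise regions) *after* the derivative filter, so
the filter window never straddles a deletion gap. Bounds are inclusive —
the most conservative reading of "variables in the range are abandoned".
The chain order for LC is COW → reduction → derivative (alignment first,
while shift resolution is finest).

## Partitioning

`kennard_stone()` selects the calibration set deterministically: the two
mutually farthest samples first, then repeatedly the sample maximizing its
minimum Euclidean distance to those already chosen; ties break to the
lowest index. The 2:1 ratio is implemented as `n_cal = floor(2m/3)`, the
only convention consistent with 61 samples splitting 40/21 and 62 splitting
41/21. Because fusion needs every block to agree on which samples are
calibration, `shared_split()` computes one split on the column-wise
concatenation of the *autoscaled* blocks (autoscaling keeps the wider,
higher-variance block from dominating the distance) and every strategy —
including the single-block models — reuses it. The split is computed on the
raw blocks, before warping: the COW reference is the calibration mean, so
the split must exist first.

## Classifiers

**PLS-DA.** `plsda_fit()` is PLS2 (NIPALS) regression of the one-hot class
matrix on the autoscaled calibration data. The number of latent variables
maximizes 7-fold cross-validated Q² (contiguous folds; ties go to fewer
LVs); Q² is chosen over classification error because it is the quantity the
permutation diagnostic plots. Zero-variance columns are dropped with a
warning. Predictions are the fitted dummy values; the hard class is the
argmax. For fuzzy fusion the predicted dummies of each sample are rescaled
affinely onto [0, 1] (row minimum → 0, maximum → 1) — the main interpretive
choice of the high-level path, since fuzzy connectives require membership
degrees in [0, 1] and PLS-DA's raw outputs are unbounded. A constant row
(no preference) maps to all 0.5. `vip()` computes the standard variable
importance in projection, with the algebraic identity `sum(VIP²) = p`
asserted in the test suite.

**Random forest.** `rf_screen()` implements the two-stage OOB screen: grow
`ntree_init` trees (default 2000) and take the smallest tree count whose
running overall OOB error attains the minimum *while no class's OOB error
exceeds its value at that minimum* — a formalization of choosing n_tree "on
all classes at the same time"; then evaluate every mtry in
`floor(sqrt(p)) ± 10` (floored square root: p = 2387 gives 48, p = 1097
gives 33), picking the lowest OOB error with ties to the value closest to
the default, then to the smaller value. Memberships are vote fractions, so
rows sum to 1. Forests are seeded; the screen is bitwise reproducible.

## Feature extraction

**PCA.** `pca_extract()` fits components on the calibration set only
(calibration means for centring) and projects validation samples onto the
calibration loadings. The component count rule — keep adding components
while 7-fold cross-validated Q²_cum (reconstruction PRESS on left-out rows)
improves by at least 0.01 — is a deterministic stand-in for proprietary
cross-validation rules in commercial chemometrics software; the exact rule
is unknowable, so the package states its own and applies it consistently.

**Boruta.** `boruta_select()` authors the all-relevant wrapper: each
iteration appends freshly reshuffled shadow copies of all still-active
variables, fits a forest, and scores permutation importance (z-scored mean
decrease in accuracy); variables beating the maximum shadow importance
register a hit; two-sided binomial tests on the hit counts, Bonferroni
corrected over the undecided variables, confirm or reject; rejected
variables and their shadows leave the pool, and anything undecided at
`max_iter` is tentative. Confirmed ∪ tentative variables are the extracted
feature set. Extraction is fitted on calibration rows only; validation
features are the corresponding column subset (or PCA projection), so no
information leaks across the split.

A note on the pure-noise behaviour: with small cohorts a noise variable can
be *genuinely* associated with the labels in the dataset at hand, and an
all-relevant method will (correctly) flag it. The false-positive control of
the binomial machinery is therefore exercised in the tests at m = 120,
where chance correlations are negligible.

## Fusion

- `low_level_fuse()` concatenates the pretreated blocks column-wise, each
  block autoscaled first (switchable) so the 2387-variable LC block cannot
  drown the narrower FTIR block in a variance-based model.
- `mid_level_fuse()` concatenates per-block extracted features (Boruta
  columns or PCA scores).
- `high_level_decide()` trains one model per (reduced) block and combines
  the per-block membership matrices: each of the four fuzzy connectives —
  maximum, minimum, average, product, applied element-wise per sample and
  class — casts an argmax vote, and the final class is the majority of the
  four votes. The connectives never define a 2–2 tie-break, so the package
  states one: highest average-operator membership, then class order. All
  operators are commutative in the block list, and unanimity is preserved:
  if every block's own argmax agrees, the fused decision returns it.

## Evaluation

`confusion()` produces one-vs-rest counts; `efficiency()` is
`sqrt(sensitivity × specificity)` per class — the geometric-mean reading of
the efficiency statistic, which reproduces the characteristic 0.71-type
values that arise when half of a small class is missed;
`total_accuracy()` reports percent correct to 2 decimals (20/21 = 95.24).
`permutation_test()` refits the PLS-DA model under `n_iter` (default 30)
label permutations with the original number of latent variables, records
R²/Q² against the correlation between permuted and original one-hot labels,
and fits a least-squares line of Q² vs correlation including the original
model at correlation 1; an intercept at or below zero is the
"not overfitting" verdict.

`run_experiment()` ties it together: one shared split, per-block
pretreatment, then 2 single-block models and 5 fusion strategies
(low-level, mid-level PCA, mid-level Boruta, high-level PCA, high-level
Boruta), each with both classifiers — 14 evaluated models, reported for
calibration and validation sets.

## The synthetic design

The generator emulates the statistical structure the analysis assumes, not
the chemistry: Gaussian peaks in the axis coordinate, per-sample quadratic
baseline drift (exercising the derivative filter), white noise, integer
retention-time shifts applied to LC peak centers (giving COW a recoverable
ground truth), and FTIR regions 1750–2670 / 3700–4000 cm⁻¹ that carry
inflated noise and no class signal (exercising band deletion). Defaults
mirror the study conditions: five origins, balanced at 12 samples per
origin, LC 7201 points / 60 min, FTIR 1737 points / 650–4000 cm⁻¹.
Per-origin counts are balanced because the real per-origin counts are
unknown beyond totals.

The key structural feature is *complementarity*: origins 1 and 2 are
confusable within each single block but separable jointly. Each block
carries one weak marker peak separating them, with opposite class offsets
(+0.15 in LC, −0.15 in FTIR), and both markers fluctuate with a shared
specimen-level latent abundance factor (sd 0.12, same draw per sample in
both blocks) that swamps the offset within a block. The cross-block
contrast of the two markers cancels the latent factor exactly, so only a
model that sees both blocks can resolve the pair — fusion demonstrably
helps, and the mid-level path benefits most because Boruta hands the
classifier exactly the marker variables. Two further choices make the
design behave: each latent marker is also the sole within-block carrier of
one strong class signal (origin 5 in LC, origin 4 in FTIR), because a
variable whose only role is a masked weak contrast is otherwise rejected by
importance-based selection (RF importance masking); and within-class
height fluctuation (sd 0.05) plus the latent factor set the difficulty of
the 1-vs-2 pair. The peak table was calibrated once to realize this
structure and is not a per-experiment tuning knob.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real peak shapes (tailing, co-elution), nonlinear
detector response, correlated (non-white) noise, multiplicative scatter in
ATR spectra, unbalanced cohorts, and batch effects. Results on this design
demonstrate that the pipeline's machinery is correct and that its fusion
logic can exploit complementary blocks; they are not estimates of
real-data accuracy.

## Problem sizes

Heavy computations in the test suite and the acceptance script run the same
five-origin design at reduced grid resolution — LC 1201 points, FTIR 869
points, shifts of sd 2 points — with forests of 300 trees (screen span ±3)
and Boruta capped at 40 iterations; one full experiment takes ~15 s. The
pretreatment bookkeeping (7201 → 2387) and COW oracle checks run at full
width. Statistical criteria (fusion synergy, Boruta recovery and null,
permutation intercept) are evaluated over 5 fixed seeds (20 for the null).

## Known limitations

- COW interpolation is linear within segments; sub-point shifts are
  approximated, not resolved.
- The PCA component-count and PLS-DA membership-rescaling rules are stated
  package conventions; other chemometrics software will differ in detail.
- `efficiency()` is undefined (NA) for a class absent from a set — small
  validation sets can produce such cells, as the report marks.
- High-level fusion reuses the four stated connectives only; no weighted or
  trained (stacking) combination is provided.
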