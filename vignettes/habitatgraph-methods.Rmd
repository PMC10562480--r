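---
title: "Habitat graphs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat graphs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: what is modeled,
which knobs matter, where the design was genuinely open and what was
decided, and what the synthetic tests do and do not demonstrate about
real imaging data.

## The habitat model

Each subject contributes one post-contrast T1-weighted slice and one
T2-FLAIR slice with per-sequence binary tumor ROI masks, assumed already
registered, bias-corrected and resampled to 1 mm isotropic pixels — the
package deliberately performs no preprocessing. Within each sequence's
ROI, intensities are scaled to $[0,1]$ by $(v - \min)/(\max - \min)$ and
modeled as a two-component Gaussian mixture. The habitat threshold is the
average of the fitted component means, $(\mu_1 + \mu_2)/2$; scaled values
strictly above it form the HIGH habitat and values at or below it the LOW
habitat. Because the scaling absorbs any affine map of the raw
intensities, the four masks (T1-high, T1-low, T2-high, T2-low) are
invariant to scanner gain and offset — a property the tests assert
directly.

Decisions where the method leaves room:

* **EM details.** `mclust::Mclust` with $G = 2$ fits the mixture; its
  model-based agglomerative initialization is deterministic, which is the
  property the pipeline actually needs (a k-means multi-start would add
  randomness to remove again). Component variances are unequal by default
  (`equal_variance = FALSE`); the constraint is exposed because the
  equal-variance fit is the natural alternative reading.
* **Boundary rule.** A scaled value exactly equal to the threshold goes
  to LOW. Ties are measure-zero for real intensities but the rule must be
  fixed for reproducibility.
* **Degenerate ROIs.** Fewer than 20 ROI pixels (configurable), a
  constant ROI, or a fit whose means are separated by less than 0.02
  scaled units (2% of the intensity range — far below any radiologically
  meaningful habitat separation) raise tagged errors rather than
  producing arbitrary masks. The pipeline records such subjects as
  missing rows.

## Centroid maps

An 8-pixel grid (8 mm × 8 mm) is overlaid on each habitat mask and every
occupied cell contributes the center of mass of its habitat pixels.
The grid is anchored at the habitat mask's *bounding-box top-left
corner*: anchoring must be defined relative to something, and the
bounding box makes centroids reproducible without whole-image
registration. The choice is validated by a translation property —
shifting a mask by exact grid multiples shifts every centroid by the same
offset. Pixel indices are 0-based, physical coordinates are index ×
spacing, and centroids are not snapped to the pixel lattice.

## MST branch-length features

Per habitat, the Euclidean minimum spanning tree over the centroids is
built (via `igraph`, Prim's algorithm — deterministic for a fixed input,
so the branch-length multiset feeding the features is reproducible even
when equal-weight trees exist). Its edge-weight distribution
$W = \{w_1, \dots, w_n\}$ is summarized by seven statistics: mean
$f_\mu$, median, *population* standard deviation
$f_\sigma = [\tfrac1n \sum (w_i - f_\mu)^2]^{1/2}$, skewness
$\tfrac{1}{n f_\sigma^3} \sum (w_i - f_\mu)^3$, kurtosis
$\tfrac{1}{n f_\sigma^4} \sum (w_i - f_\mu)^4$ (non-excess: large normal
samples give ≈ 3), the ratio $f_r = \max(W)/\min(W)$, and disorder
$f_\sigma / f_\mu$. The $1/n$ normalization is kept exactly as the
formulas are written, not sample-corrected. When $f_\sigma = 0$ the
skewness and kurtosis expressions are $0/0$; both are defined as 0. A
habitat with fewer than two centroids yields seven missing values —
missingness is data, handled downstream by imputation, never silently
zeroed. With four habitats this gives the fixed 28-feature block.

## Delaunay triangulation and graph run lengths

The centroids of all four habitats are combined into one labeled map and
Delaunay-triangulated (`deldir`); each edge is typed by its unordered
endpoint-habitat pair. With four labels there are exactly 10 edge types,
indexed stably: the four same-label types first in habitat order, then
the six mixed pairs lexicographically. Two practical points:

* Grid centroids of full cells sit at cell centers, so centroid maps
  contain cocircular lattices; `deldir`'s deterministic handling of these
  degeneracies is the reason an external triangulation engine is used at
  all, and the empty-circumcircle property is still verified directly on
  every triangle in the tests.
* A grid cell fully covered by one habitat of *each* sequence produces
  bitwise-identical centroids for two habitats. Duplicated coordinates
  are perturbed deterministically by multiples of $10^{-6}$ mm in $x$
  before triangulation (edge lengths use the original coordinates), so a
  fixed input always yields the same edge set and no vertex is silently
  dropped.

The graph run-length matrix $G(t, l)$ counts, for every node $v$ and
every edge type $t$ with at least one type-$t$ edge at $v$, exactly one
run: its length is the largest number of consecutive type-$t$ edges along
any simple path starting at $v$, capped at `L_max` (default 10, a
tractability bound on the exhaustive longest-path search that these small
graphs never approach in practice). A circular window of radius
`window_radius_mm` centered at $v$ limits how far a run may extend: nodes
reached beyond the first edge must lie strictly within it. The first
edge always counts, so run lengths are at least 1; shrinking the window
therefore drives every run to length 1 (and LPE to 1) rather than
deleting runs, and the total run count $n_r$ always equals the number of
(node, incident edge type) pairs. The window default is unbounded — the
whole map — since no radius is inherent to the method; it is a
configurable locality scale in mm.

Features: $SPE = \tfrac{1}{n_r}\sum_{t,l} G(t,l)/l^2$,
$LPE = \tfrac{1}{n_r}\sum_{t,l} G(t,l)\,l^2$,
$ETN = \tfrac{1}{n_r}\sum_t (\sum_l G(t,l))^2$,
$PLN = \tfrac{1}{n_r}\sum_l (\sum_t G(t,l))^2$, plus per-type $SPE(t)$
and $LPE(t)$ with the sums restricted to type $t$ and normalized by that
type's run count $n_r(t)$ — the only reading that yields ten distinct
per-type values. Types absent from a subject's map give missing per-type
features. Total: 24 features, hence 52 per subject.

## Classification harness

Binary outcomes are formed either by thresholding survival at 12 months
(label 1 iff survival > 12) or by splitting a continuous score at the
cohort median (label 1 iff score > median; scores at the median are the
low class). Evaluation is stratified $k$-fold cross-validation (default
5) of a random forest (default 10,000 trees; the examples and tests use
fewer — forests stabilize well below that on these feature counts, and
the default is kept for fidelity to routine practice with this method).
Within each training fold, missing features are imputed by the
*training-fold* median — held-out data never contribute imputation
statistics — and class imbalance is removed by resampling the minority
class with replacement up to the majority count, a seed-controlled
implementation of class-proportional sampling.

Pooled out-of-fold probabilities feed a threshold sweep over all unique
values: AUC by the trapezoidal rule (provably equal to the pairwise
Mann–Whitney statistic, which the tests assert exactly, with ties worth
one half), the operating point maximizing TPR + TNR (Youden; ties broken
toward the smallest threshold), accuracy from the confusion matrix at
that cutoff, and MAE defined as the mean absolute difference between
out-of-fold probability and 0/1 label — an interpretation, since MAE for
a probabilistic classifier admits variants. Whether reported TPR/TNR
should come from pooled out-of-fold predictions or be averaged across
folds was an open choice; pooling was chosen because the Youden cutoff is
then defined on a single ROC curve. Gini importances come from one
forest refit on the full (imputed) table.

## The phantom generator

Synthetic subjects exist so that every stage — and the pipeline's ability
to recover a *planted spatial effect* — is testable without patient
images. A phantom is a square image (default 96 px) with an elliptical
ROI (default semi-axes 34 × 26 px, ~2,800 ROI pixels, comparable to a
large glioblastoma cross-section at 1 mm) shared by both sequences.
In-ROI intensities are drawn from a per-sequence two-component normal
mixture; defaults (T1: 200/500 ± 35, T2: 300/650 ± 40 on an arbitrary
scanner scale, `high_fraction` 0.4) separate the components by ≈ 8 SD so
that habitat recovery is essentially limited by the threshold, not by
overlap. Background outside the ROI is Gaussian noise at 10% of the
low-component mean — masks exclude it; it exists only so written image
files look plausible.

The `clustering` knob controls spatial arrangement of the high
component: a fraction `clustering` of its pixels are the ones nearest to
`blob_count` (default 3) blob centers — rejection-sampled inside the ROI
with pairwise separation of at least one blob radius, so blobs do not
collapse onto each other — and the rest are scattered uniformly. At 0
the high habitat is uniform over the ROI; at 1 it is fully concentrated.
Cohorts plant a class effect by shifting `clustering` (and optionally
`high_fraction`) for class 1; the study conditions used throughout the
tests are 30 subjects per class with clustering 0 vs 0.8, and a null
twin with no shift. Per-subject seeds are derived deterministically from
the cohort seed, and ground-truth component masks are returned with each
phantom.

What the phantoms do *not* emulate: 3D anatomy, bias fields, scanner
noise correlation, partial-volume effects, non-elliptical or
sequence-discordant ROIs, and any realistic relationship between spatial
clustering and actual survival. Passing tests therefore demonstrate that
the implementation is correct and that the features detect spatial
clustering of habitats when it exists — not that they are prognostic in
patients.

## Problem sizes and numerical conventions

The test suite and the reproduction script use sizes chosen to exercise
the method honestly while remaining quick on a laptop: 96-px phantoms,
cohorts of 30 + 30 with 1,000-tree forests for the planted-effect and
null checks, exhaustive MST enumeration up to 7 points (all $n^{n-2}$
labeled trees via Prüfer sequences), exhaustive run-length enumeration up
to 12 nodes, and 16-decimal agreement tolerances for closed-form
fixtures. Degenerate inputs follow one rule everywhere: detectable
nonsense (empty ROI, constant intensities, collinear centroid maps,
single-class labels) raises a tagged error at the operation level, and
the subject-level pipeline converts those errors into logged missing
values so one bad subject never aborts a cohort.

## Known limitations

* 2D only, by design: the method analyzes the single slice with maximal
  tumor area per sequence (for 3D files, the package picks that slice,
  ties to the lowest index, and uses the same index for both sequences —
  assuming registered volumes).
* Whether runs should be counted per (node, incident edge type) — as
  implemented — or once per incident *edge* is ambiguous in the run-length
  construction this feature family descends from; the per-node-type
  reading is fixed, documented, and enforced by the conservation
  invariant in the tests.
* The min/max ratio $f_r$ is, despite its conventional name, computed as
  $\max(W)/\min(W)$, following the defining formula.
* Immune signature scores are accepted precomputed; the package does not
  compute ssGSEA enrichment from expression data.
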