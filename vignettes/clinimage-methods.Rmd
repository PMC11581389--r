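---
title: "Predicting invasive disease events from clinical data as images: methods and design notes"
author: "ClinImage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ClinImage methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a first invasive breast-cancer diagnosis, a fraction of patients
experience an *invasive disease event* (IDE) — a recurrence, a distant
metastasis, a contralateral or a second tumor — within 5 or 10 years.
Routine clinical practice records a compact set of clinical and
histopathological variables (age, receptor status, grading, tumor size,
nodal involvement, therapy flags, ...); ClinImage implements a pipeline
that predicts the binary IDE outcome at a fixed horizon from 28 such
features, one patient at a time.

The pipeline's distinctive step is a *tabular-to-image* transformation in
the DeepInsight tradition: every feature is assigned a fixed pixel
location learned from the training set, each patient becomes a small
grayscale image whose pixel intensities are that patient's normalized
feature values, and a convolutional network pretrained on unrelated
images is used as a frozen feature extractor on those images.  The
deep-feature representation is then filtered, stabilised and classified
with a linear SVM.

## Pipeline

Given an encoded training matrix $X \in \mathbb{R}^{n \times 28}$:

1. **Normalization.** Per-feature min-max scaling to $[0,1]$ fitted on
   training rows; at application time out-of-range values are clipped and
   features constant in training map to 0.
2. **Feature embedding.** Each *feature* is a point in patient space (a
   column of $X$).  With the Gaussian kernel
   $K_{ij} = \exp(-\lVert f_i - f_j\rVert^2 / 2\sigma^2)$, the
   double-centred kernel matrix is eigendecomposed and each feature gets
   the coordinates $(u_{i1}\sqrt{\lambda_1},\, u_{i2}\sqrt{\lambda_2})$
   on the top two components (kernel PCA scores).  $\sigma$ defaults to
   the median pairwise distance among feature points (median heuristic) —
   scale-free and stable; it is configurable.
3. **Geometry.** The convex hull of the 28 embedded points (monotone
   chain; collinear boundary points excluded), then the minimum-area
   enclosing rectangle (rotating calipers over hull-edge orientations;
   angle normalized to $[0^\circ, 90^\circ)$, ties broken toward the
   smaller angle).  Coordinates are rotated so the rectangle's longer
   side lies horizontal.
4. **Rasterization.** The rectangle is mapped affinely onto a
   `grid = c(50, 50)` raster (half-open pixel intervals, boundary points
   clamped inside, 0-based row/col with origin top-left).  Features
   sharing a pixel form a *collision group*; a collision pixel carries
   the arithmetic mean of its features' values — value-preserving and
   order-independent.  50×50 leaves 28 features essentially
   collision-free while keeping images small.
5. **Deep features.** Each image is resized to 227×227 by separable
   bilinear interpolation (half-pixel-centre convention; constants are
   preserved exactly), replicated to 3 channels, and passed through the
   AlexNet front end: conv1 (96 filters 11×11, stride 4) + ReLU, max-pool
   3×3 stride 2, conv2 (256 filters 5×5, padding 2) + ReLU, max-pool 3×3
   stride 2.  The spatial chain is 227 → 55 → 27 → 27 → 13, so pool2
   emits 13×13×256 = 43,264 activations, flattened in a fixed order
   (index = row + 13·col + 169·channel, 0-based).  By default the
   convolution weights are He-scaled Gaussians under a fixed seed with
   zero biases, so the package is fully reproducible offline; a
   user-supplied weight file of the same shapes (e.g. exported from a
   pretrained AlexNet) can be plugged in via `weightsPath`.  Every
   geometric and statistical property of the pipeline is weight-agnostic;
   the headline discriminative power on real data is not, and requires
   pretrained weights.
6. **Selection.** A two-sided Wilcoxon rank-sum test per deep feature
   (exact for small tie-free groups, tie-corrected normal approximation
   otherwise, no continuity correction), keeping features with
   $p < 0.005$ (raw, no multiplicity adjustment — the threshold is read
   as a hard filter, not an inference).  A Random Forest (500 trees,
   $\lfloor\sqrt{p}\rfloor$ candidates per split, impurity importance,
   fixed seed) then keeps the features whose Gini importance is
   *strictly greater* than the median importance of the filtered set —
   with $k$ distinct importances exactly $\lfloor k/2\rfloor$ survive,
   with all importances equal nothing does.
7. **Stability.** The filter + Gini selection is refitted on the training
   portion of every fold of a stratified 10-fold × 10-round CV, and only
   the *intersection* of all 100 selections is retained.  Per-fold SVMs
   evaluated on the held-out folds provide the CV metric distributions
   (median and quartiles).
8. **Classifier.** A linear SVM (fixed $C = 1$, no internal tuning) on
   the stable features, standardized with training statistics.  Decision
   scores are signed distances, positive toward the IDE class.
9. **Evaluation.** Trapezoidal ROC AUC (ties half-credit; identical to
   the rank-sum statistic $U/(n_1 n_2)$); the operating threshold
   maximizes Youden's $J = \text{sensitivity} + \text{specificity} - 1$
   over all midpoints between adjacent distinct scores plus $\pm\infty$
   (ties take the lowest threshold, `score >= threshold` predicts
   positive), and accuracy/sensitivity/specificity/precision are reported
   there.  A label-permutation test (100 permutations) recomputes the
   hold-out AUC under shuffled labels; *both* add-one estimators are
   reported — the standard convention counts permuted AUCs $\ge$ the
   observed one, the study convention counts those $\le$ it (which
   approaches 1 for a model far above its null; the package treats the
   standard convention as the decision-relevant one).  Patient-by-patient
   Spearman correlation and p-value matrices are available as cohort
   diagnostics.

Hold-out discipline is structural: the split is stratified (per class,
`round(0.8 · class size)` rounded half up into training), and every
fitted artifact — normalization bounds, embedding, rectangle, pixel
assignment, filter, selection, SVM — derives from training rows only.
Imputation replaces the missing cells of a patient with those of the
*complete* record at minimum Euclidean distance over the patient's
observed features, after per-feature min-max scaling on the reference
cohort (ties to the lowest donor index); test patients are imputed
against the training cohort.

## The synthetic cohort generator

The study cohort is private, so the package ships a simulator that
reproduces the published schema and marginal distributions: 6 continuous
features drawn through a piecewise-linear quantile function interpolating
the published (min, q1, median, q3, max) — this matches all printed
quantiles exactly in expectation without asserting a distributional
family — and 22 categorical features drawn from the published level
percentages (renormalised after excluding missing-value rows).  Class
prevalences default to the study's: 168/528 at 5 years, 251/375 at 10
years.  Missingness is completely at random at a configurable rate.

The class-conditional signal is the package's own construction (the study
never characterizes class-conditional distributions): continuous features
shift by `delta` IQRs (clipped to the domain), categorical features tilt
their level probabilities toward higher-coded levels.  `simulateCohort()`
uses an additive tilt and raises a configuration error when a probability
would leave $[0,1]$; `simulateSeparableCohort()` uses an exponential
tilt, feasible for every `delta` and any number of informative features
up to 28, and returns the ground-truth informative set for recovery
experiments.

What the simulator does *not* emulate: joint dependencies among features
beyond their marginals (the strong between-patient Spearman correlations
arise naturally from shared marginals, without an explicit copula),
informative missingness, temporal drift in treatment policy, and any
real biological coupling between features and outcome.  Tests passing on
synthetic cohorts therefore validate the machinery and its statistical
calibration — not clinical performance.

## Numerical choices and tie-breaks

* Eigenvector signs: each embedding component is flipped so its
  largest-magnitude loading is positive (reproducible layouts).
* Degenerate geometry: an all-collinear embedding yields a two-point
  "hull" and a zero-height rectangle; rasterization collapses the flat
  axis to pixel 0.
* Rank-sum filter: exact Wilcoxon p-values for tie-free columns with both
  groups under 50, otherwise the tie-corrected normal approximation; a
  constant column gets $p = 1$.
* The convolution forward pass runs in single precision (im2col + BLAS
  sgemm); activations feed rank statistics downstream, where float
  precision is far beyond sufficient.  Extraction is bitwise
  deterministic for fixed weights.
* JSON artifacts serialize doubles at 17 significant digits, so reloaded
  layouts and models reproduce scores bit-for-bit.
* One master seed derives all stage seeds as
  `(master + 1009 · stage_index) mod (2^31 - 1)`; any stage can be rerun
  in isolation.

## The permutation-test refit policy

Under each permuted labelling the univariate filter, the Gini selection
and the SVM are refitted on the training partition and the hold-out AUC
is recomputed — an honest null for the selection + classification step.
The 10×10 stability intersection is *not* re-run per permutation: that
would multiply the full CV by the permutation count (10,000 Random-Forest
fits) for no change in the null's interpretation, since the intersection
can only shrink the refitted selection.  A clearly labelled `"rescore"`
mode (fixed model, permuted labels) exists for quick calibration
experiments.

## Importance density and the intersection rule

A finding worth knowing before using the intersection rule on
high-dimensional deep features: when the class signal is very strong,
Random-Forest trees purify in one or two splits, each tree touches only a
handful of the filtered features, and the Gini importance vector becomes
sparse — which features are nonzero then varies fold to fold, and the
all-folds intersection collapses to the empty set.  With a moderate
signal (around 1 IQR on a handful of features) trees are deep, importance
mass spreads across the informative features consistently, and the
intersection is stable and non-empty.  The package raises an explicit
error with per-fold diagnostics when the intersection is empty; the
degenerate scheme (`nFolds = 1, nRounds = 1`), equivalent to a single
selection pass, is the pragmatic configuration for strongly separated
data.

## Discreteness of the filter under the null

Pool2 activations are zero-heavy (most image pixels are background), so
the rank-sum statistic of a typical deep feature has few attainable
values and its p-value distribution is discrete.  Under a null labelling
the number of features reaching $p < 0.005$ is then far below the
nominal $0.005 \times 43{,}264$, frequently zero — the pipeline correctly
reports an empty selection rather than inventing a model.  Two
consequences are built in: the permutation test scores a permuted
labelling that kills every feature as a chance draw (AUC 0.5), and the
shipped chance-level calibration experiment runs the filter at 0.05 so
that a null model exists whose hold-out AUC can be measured.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run entirely on synthetic
cohorts at desk scale, chosen once as follows: the full default
experiment at $n = 600$ with 5-year-like prevalence, 5 informative
features at a 1-IQR shift, 10×10 CV and 100 refit permutations; signal
recovery at $n = 600$, `delta = 2`, 10 seeds, degenerate scheme;
chance-level calibration at $n = 320$ effect-free with a 0.4 training
fraction across 10 seeds; permutation-p uniformity on 100 small null
matrices; the acceptance script at the 10-year study size (251/375).
Geometry and embedding oracles (brute-force hull, orientation-sweep
rectangle, dense eigendecomposition) run on 25–30-point instances at
tolerance 1e-8.

## Known limitations

* Random extractor weights are the offline default; conclusions about
  real-data discrimination require pretrained weights supplied by the
  user.
* The intersection rule is fragile in the strong-signal regime (above).
* Youden-point precision is undefined when no patient is predicted
  positive; it is reported as `NA` in that corner case.
* The published headline metrics of the originating study (hold-out AUC
  above 90% on the private institutional cohort) are not reproducible
  without that cohort and are not targets of the shipped experiments.
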