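---
title: "Methods: swarm-selected fuzzy C-means classification of cervical cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-selected fuzzy C-means classification of cervical cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoswarm)
```

## The problem

Pap smear screening classifies single cervical cells into seven categories:
three normal ones (superficial/preliminary squamous, moderate squamous,
columnar) and four precancerous-to-malignant ones (mild, moderate and severe
dysplasia, and carcinoma in situ). The cytological signature of progression
is well known: the nucleus enlarges and darkens with grade, the cytoplasm
shrinks, and the nucleus-to-cell area ratio (N/C ratio) rises. `cytoswarm`
implements a hybrid classifier for segmented single-cell images (RGB pixels
plus expert-validated nucleus and cytoplasm masks): morphometric and texture
features are extracted per cell, a quantum-behaved binary swarm selects a
feature subset using the downstream classifier's validation F1 as the
wrapper objective, and a fuzzy C-means (FCM) model classifies cells with
the selected features.

Segmentation is out of scope throughout: masks are inputs, produced either
by an upstream tool or by the package's synthetic generator.

## Features

Thirteen morphometric scalars are computed from the gray image
(luma `0.299 R + 0.587 G + 0.114 B`, rounded half-up) and the two masks:
nucleus area, bounding-box length and width, aspect ratio, perimeter,
roundness, homogeneity, brightness; cytoplasm max/min/mean intensity; cell
area; and the N/C ratio. Several of these needed a concrete convention,
chosen so that hand-countable fixtures are exact:

* **Perimeter** is the count of nucleus pixels with at least one 4-neighbor
  outside the mask. A 10x10 square therefore has perimeter 36.
* **Roundness** is the circularity `4*pi*A/P^2` under that perimeter. Note
  that boundary-pixel counting underestimates the Euclidean perimeter of
  smooth shapes (a rasterized disk of radius 20 has 112 boundary pixels
  against a true circumference of 125.7), so disk roundness computes to
  about 1.26 rather than 1; the convention is kept because it makes the
  square fixtures exact and is applied uniformly, so it is a consistent
  shape statistic rather than an unbiased circularity estimate.
* **Homogeneity** is the histogram energy `sum(p_i^2)` over the 256-bin
  normalized nucleus histogram: 1 exactly for uniform intensity, small for
  spread-out histograms.
* **Length/width** come from the axis-aligned bounding box with
  `L >= W`, so the aspect ratio `W/L` always lies in (0, 1].

**Texture (BHF).** The binary histogram Fourier block is the
rotation-invariant LBP-histogram-Fourier construction: P-bit codes compare
each circular neighbor (radius R, bilinear interpolation) to the center
pixel, with ties counting as 1; the normalized histogram of uniform
patterns is indexed by (ones-count n, rotation index r), with three special
bins (all-zeros, all-ones, non-uniform); each ones-count row is Fourier
transformed along r and the magnitudes of frequencies `0..P/2` are kept.
Rotating the image circularly shifts each row, so the magnitudes are
rotation invariant while the raw histogram is not — the test suite checks a
90-degree rotation, which is exact on the pixel lattice. Defaults P = 8,
R = 1 give 7 x 5 magnitudes + 3 bins = 38 entries. A constant region
produces all-ones codes only (by the tie rule), so its BHF vector is
independent of the constant.

**Feature groups.** Subset selection operates on 14 groups: the 13 scalars
plus the whole BHF block as one selectable unit. The classical pruned set
(`"pruned7"`) keeps nucleus area, roundness and brightness, cytoplasm
brightness, cell area, the N/C ratio, and BHF — seven features counting BHF
as one.

## The classifier: fuzzy C-means

FCM is the standard Bezdek alternating optimization of
`J = sum_ij u_ij^m ||x_i - c_j||^2` with memberships
`u_ij = [sum_k (d_ij/d_ik)^(2/(m-1))]^(-1)` and weighted-mean centroid
updates. Defaults: C = 7 clusters (one per class), fuzziness m = 2,
tolerance 1e-5 on the objective change, 300 iterations maximum, and 5
seeded restarts keeping the best final objective. Because FCM is
unsupervised, it becomes a classifier by mapping each cluster to the
majority class of its hard-assigned (argmax membership) training points;
ties break to the lowest class index and empty clusters fall back to the
global majority class with a warning. Features are z-scored with training
statistics before clustering — pixel counts, gray levels and ratios are
incommensurable, and unscaled Euclidean distance would be dominated by the
area features. Degenerate cases are fixed by convention: a point coincident
with a centroid gets membership 1 there; constant features get sd 1 in the
scaler; duplicate initial centroids are jittered apart by 1e-6.

The objective trace is non-increasing within each restart (a property of
the alternating updates, asserted on random datasets), and as `m -> 1` the
soft argmax converges to nearest-centroid assignment (tested at m = 1.05).

## The feature selector: quantum-behaved binary swarm

No update equations exist in the classical descriptions of this "quantum
grasshopper" family beyond the wave-function/global-best narrative, so the
package adopts the standard quantum-behaved particle swarm (QPSO) update,
which matches that narrative and is velocity-free:

```
p   = phi * pbest + (1 - phi) * gbest,      phi ~ U(0,1) per dimension
x'  = p +/- beta * |mbest - x| * ln(1/u),   u ~ U(0,1), sign w.p. 1/2
bit = 1  iff  v < 1/(1 + exp(-x')),         v ~ U(0,1)
```

with `mbest` the componentwise mean of all personal bests and the
contraction-expansion coefficient `beta` on a linear schedule 1.0 -> 0.5.
All-zero masks are repaired by setting one uniformly chosen bit. Defaults:
20 particles, 50 iterations, and the first particle seeded with the
all-ones mask, which guarantees the selected subset never scores below the
all-features baseline on the internal split.

**Fitness.** A mask's fitness is the macro-F1 of the FCM classifier
fitted on 70% of the training data and evaluated on the other 30%
(stratified, fixed by one split seed for the whole run), minus a parsimony
penalty `lambda * (set bits / d)` with `lambda = 0.01`. The penalty biases
toward smaller subsets without being able to override a 1-point F1
difference until subsets differ by more than a full group; it encodes the
preference for a pruned feature set absent any published criterion. Fixing
the split (rather than resampling per evaluation) makes fitness a
deterministic function of the mask, so global-best monotonicity is
meaningful and evaluations can be memoized.

For verification the package ships `exhaustive_subset_search()`, a
brute-force oracle over all nonempty masks (d <= 16, ties to fewer bits
then lexicographic order). On random 10-bit fitness tables the swarm (30
particles x 100 iterations) reaches within 2% of the exhaustive optimum in
at least 9 of 10 seeds.

## Evaluation protocol

The experiment (`run_experiment()`) follows a five-stage design: data,
stratified 70/30 partition, FCM on all features, swarm selection on the
training part plus FCM on the selected groups, and evaluation of both
models on the held-out 30%. Metrics: the K x K confusion matrix (rows =
actual), one-vs-rest precision/recall/F1 with unweighted macro averages
(chosen because the class distribution is imbalanced), accuracy, Cohen's
kappa, and a Brier-style membership MSE
`mean_i ||u_i - onehot(y_i)||^2 / K` (the literature this follows reports
an undefined "mean square error"; the membership Brier score is the natural
choice for a fuzzy classifier and is documented in the report schema).
The seven classes also collapse to normal = {preliminary squamous, moderate
squamous, columnar} versus cancerous = the four dysplastic/malignant
classes, giving binary accuracy, sensitivity and specificity. Zero-division
conventions are explicit: a never-predicted class gets precision and F1
zero with a warning; undefined binary metrics are reported as `NA`; kappa
is 0 when expected agreement is 1. Stratified 12-fold cross-validation is
available via `kfold_cv()`, reducing k with a warning when the smallest
class is smaller than k.

## The synthetic generator

No public quantitative morphology exists per class, so the generator's
profiles are free parameters that encode the qualitative progression:
across mild -> moderate -> severe dysplasia -> carcinoma in situ the
nucleus radius mean rises (10, 13, 16, 18 px at a 128 px frame), the
nucleus intensity falls (95, 80, 65, 50 gray levels), the cytoplasm radius
falls for severe grades, and the texture amplitude rises. Normal classes
have small bright nuclei in large (squamous, 27-30 px) or small (columnar,
14 px) cytoplasm. Cells are two nested rasterized ellipses (random
orientation, eccentricity within a per-class range, the nucleus redrawn up
to 100 times until it fits inside the cytoplasm, then an error); pixel
intensities are class means plus Gaussian noise (sd 8-10) plus one
band-limited sinusoid scaled by the class texture amplitude; RGB channels
add zero-luma chroma offsets (bluish nucleus, pinkish cytoplasm) so the
gray-level targets are preserved by the luma transform. A metadata tag of
0.197 um/pixel is recorded but never used in computation. One master seed
expands to per-image sub-seeds by stable hashing of (seed, class, index),
so generation order cannot change outputs. Two presets reproduce the
per-class counts of the reference single-cell collections (1614 and 1500
images) for manifest arithmetic.

What the generator does *not* emulate: overlapping cells, debris,
staining variability, imaging artifacts, or real Herlev intensity
statistics. Passing tests therefore demonstrate the correctness and
self-consistency of the pipeline — not clinical performance on real smears.

## The planted-features testbed

Selection recovery is measured on a simulated design where informative
column j shifts only class j by 3 noise standard deviations (one-hot class
means) and the remaining columns are pure noise. With 7 classes and 7
informative columns, dropping two informative columns makes two classes
indistinguishable, so at least six of the seven are jointly necessary —
this is what makes "the selected mask overlaps the informative set"
a well-posed criterion. An earlier design with independently drawn class
means was discarded because its informative features were so redundant that
a three-feature subset was genuinely optimal.

## Numerical choices and problem sizes

* Seeds: every stochastic stage (generation, splits, FCM restarts, swarm)
  derives a sub-seed from one master seed by stable hashing below 2^31.
* The wrapper's internal FCM uses a lighter budget (2 restarts, 60
  iterations, tolerance 1e-4) than the final model fit (5 restarts, 300,
  1e-5); the swarm memoizes fitness per mask.
* Test and acceptance simulations use 20 cells or samples per class
  (140-210 total), 10 seeds per property, and the default swarm; these
  sizes keep every statistic stable while the whole suite runs in minutes.
* The `run_experiment()` defaults (70/30 split, C = 7, m = 2) are the
  protocol defaults, not tuned values.

## Known limitations

* FCM is a weak classifier when many uninformative features are included —
  this is precisely the regime the wrapper selection repairs, and the
  with/without comparison quantifies it.
* The boundary-pixel perimeter biases roundness upward for smooth shapes
  (see above); comparisons are only meaningful within this convention.
* The swarm is a stochastic heuristic: the oracle-equivalence guarantee is
  statistical (9/10 seeds within 2% on small instances), not a proof of
  optimality.
* Cluster-majority labeling can leave a class unpredictable when two
  classes share a cluster; macro-F1 and the zero-division conventions make
  this visible rather than hiding it.
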