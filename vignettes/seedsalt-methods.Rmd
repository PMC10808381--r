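---
title: "Methods: plate segmentation, seed features and consensus classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate segmentation, seed features and consensus classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedsalt)
```

`seedsalt` classifies seed plates as salt or non-salt from a single RGB
image. This vignette documents the model and the numerical choices the
package makes, what the synthetic data emulate (and what they do not),
and the problem sizes used by the test suite and the acceptance script.

## Segmentation

A plate image is binarized on one channel — red, green, blue, or grey,
where grey is the rounded mean of the three. A pixel is foreground iff
its value is `>= threshold` (`bright_objects`) or `<= threshold`
(`dark_objects`). With `threshold = "otsu"` the boundary is found by
exhaustively maximizing the between-class variance
$w_0 w_1 (\mu_0-\mu_1)^2$ over all 256 split points of the
(ROI-restricted) histogram; ties go to the smallest boundary, and a
constant image — where no split exists — yields an empty mask rather than
an arbitrary one. The polarity conventions make the two foreground
definitions complementary on the same Otsu split.

Connected components are identified by combined contour tracing and
region labeling, implemented in C++: a single raster scan launches a
Moore-neighbourhood (8-neighbour) contour trace at each first-met outer
boundary pixel, traces hole boundaries so that holes can never seed
spurious components, and lets interior pixels inherit the label to their
left. Design choices the method leaves open were fixed as follows:

* **Connectivity.** Foreground 8-connected, background 4-connected — the
  standard companion of Moore tracing. Two seeds touching only
  diagonally therefore merge; the package deliberately has no watershed
  split, and a clump counts as one region.
* **Label order.** Labels are consecutive from 1 in raster-scan order of
  first encounter, making tie-breaks deterministic.
* **Contours.** Each outer contour is a closed cycle, clockwise in image
  coordinates (row down, column right). An isolated pixel's contour is
  that single pixel.
* **Holes.** A seed is the interior of its outer contour: background
  pockets enclosed by a region (glare in back-lit images) are filled
  before any feature is computed, so area and perimeter remain
  well-defined.
* **ROI.** The dish circle is never auto-detected; it is part of the
  reusable detection setup, as is the area gate (`min_area`,
  `max_area`) that rejects debris and the dark dish surround of back-lit
  images.

The three presets (`FLUO`: red channel, bright objects; `VISBACK`: grey,
dark objects; `VISFRONT`: grey, bright objects; all Otsu, area gate
30–5000 px) are package defaults: the test suite requires each to
segment its mode's synthetic plates with recall ≥ 0.99, which is the
testable stand-in for "adjust until the seeds are identified".

## Morphological and colorimetric features

Per (hole-filled) region the package computes area $A$ (pixel count),
perimeter $P$ (polygonal length of the outer contour through pixel
centres: 1 per axial step, $\sqrt2$ per diagonal), circularity $P^2/A$,
compactness $A/P$, the major and minor axes, and eccentricity
major/minor (≥ 1 by construction — note this is an axis ratio, not the
classical ellipse eccentricity). The axes are $2\sqrt{\lambda_{1,2}}$
from the eigenvalues of the $2\times2$ second central moment matrix of
the pixel coordinates; for a solid ellipse with semi-axes $a \ge b$ the
coordinate variance along the major axis is $a^2/4$, so the estimates
recover the semi-axes, and twice the axes proxy physical seed length and
width. Degenerate single-row or single-column regions floor the minor
axis at 0.5 px so the eccentricity stays finite; a single-pixel region
has perimeter 0 and an undefined (`NA`) compactness.

Colour features are computed over the same pixel set: the grey histogram
peak (0–255 bin of rounded $(R+G+B)/3$ with maximal count, smallest bin
on ties), quartiles of grey and of each channel — by linear interpolation
between closest order statistics, a choice the original description
leaves open but which the whole test suite uses consistently — and the
dominant hue class among $K = 16, 32, 64$ equal divisions of the HSB hue
circle. Hue lives in $[0, 360)$ with floor binning; zero-saturation
pixels are assigned hue 0 and ties go to the smallest class index, so
the features are deterministic.

## Calibration

The pixel scale comes from the dish inner diameter (8.50 cm):
`px_per_cm = diameter_px / 8.5`, kept at full precision internally.
Printed scales are truncated to two decimals (846.50 px gives "99.58",
1812 px gives "213.17"), which `format_scale()` reproduces; truncating
internally would compound rounding error through the length/width
conversion. (With the fluorescent calibration, a printed mean major axis
of 9.76 px corresponds to 2·9.76/99.58 ≈ 1.96 mm, not the 1.95 mm
sometimes quoted — an inconsistency of the published inputs, not of the
arithmetic.)

## The classifier consensus

Each of 13 classifier families is fitted to the standardized feature
columns of the chosen attribute subset (all 23, the 7 morphological, or
the 16 colorimetric). Standardization (zero mean, unit variance on the
training data; constant columns dropped) matters for the
nearest-neighbour and kernel members. The families map to established
implementations — naive Bayes (`e1071`), multilayer perceptron (`nnet`,
size 6, decay 5e-3), support-vector classifier (`kernlab`, RBF, C = 1),
1-nearest-neighbour (`class`), entropy-split and Gini-split pruned trees
and a one-level stump (`rpart`), an unpruned tree (`tree`), a logistic
model (`stats::glm`, the single-leaf case of a logistic model tree), a
100-tree random forest (`randomForest`) and a single random tree
(`ranger`) — plus two in-package nearest-neighbour voters: a
generalized-distance voter weighting all training instances by
$e^{-d/b}$ with $b$ the median distance, and a locally weighted voter
over the 50 nearest instances with linear kernel weights. The original
hyperparameters are unreproducible, so members use these documented
defaults with a fixed RNG seed; the classification claim rests on the
consensus, not on any single member's tuning. A majority-class ZeroR
baseline is available (`zero_rule()`) but is never part of the
consensus, reflecting its chance-level seed accuracy.

Each algorithm votes with the percentage of a plate's seeds it labels
salt; the consensus is the unweighted mean of the 13 percentages and the
plate is salt iff the consensus is *strictly* greater than 50 — an exact
50 is non-salt. Averaging salt percentages rather than paired
salt/non-salt pairs is the only non-redundant reading for binary labels:
the complement percentages carry no extra information. Hard labels are
used throughout (probabilistic members threshold at 0.5), because the
consensus is defined on label percentages.

## Evaluation

With salt as the positive class, the five metrics are accuracy,
sensitivity, specificity, precision and F1
($2PS/(P+S)$). Ratios with zero denominators are reported as `NA`,
never coerced to 0. Published two-decimal tables mix rounding and
truncation, so comparisons against printed values accept either display
(`format_metric()`).

Fisher's exact test is two-sided (sidedness is a package choice, stated
here), computed by exhaustive hypergeometric enumeration at fixed
margins: all tables whose probability is at most the observed table's,
with a 1e-7 relative slack against floating-point ties, contribute to
p. Degenerate margins give p = 1.

Cross-validation splits at the *plate* level — seeds of one plate never
appear on both sides of a fold — stratified by condition and shuffled by
the seed, with k = 10 by default. Confusion counts are pooled over folds
(micro-averaged) and the metrics computed once, matching how single
metric values over a full plate collection are reported. A training fold
that loses one class is skipped with a warning rather than silently
retrained.

## What the synthetic plates emulate

The generator draws non-overlapping filled ellipses on a circular dish
and adds per-pixel Gaussian noise. Defaults were chosen once, from the
published imaging conditions, and are not tuned per test:

* 900 × 900 px image, dish radius 423 px — about 99.5 px/cm, echoing the
  fluorescent calibration;
* 90 seeds per plate, the observed average for 0.1 g of seeds (50–125
  expected per plate);
* non-salt semi-major axis ~ N(9.8, 1) px and aspect ratio ~ N(1.9,
  0.15), matching the published mean axes (9.76/5.17 px) and seed area
  (~150 px);
* FLUO optics: near-black background, seed signal concentrated in the
  red channel (~N(120, 15) per seed), almost none in blue; VISBACK:
  bright back-lit dish, dark seeds, dark surround outside the dish (so
  the rim-rejection path is exercised); VISFRONT: mid-grey background,
  brighter textured seeds;
* the default salt effect, under FLUO only: +30 % on the semi-major
  axis mean and +40 on the seed red mean — the direction and rough
  magnitude of the published group differences; back-lit and top-lit
  defaults carry no class effect, where no consistent pattern was
  observed.

Placement is rejection sampling with bounded retries (ellipses fully
inside the dish, bounding circles separated by ≥ 2 px); an
over-crowded spec fails with a clear error. Generation is bit-identical
for a given seed.

What the simulator does *not* model: touching or overlapping seeds,
photorealistic texture, specular glare, uneven illumination, barcode
labels, or the between-batch variation of real growing seasons. Passing
the synthetic suite therefore demonstrates that the pipeline's
machinery — segmentation, features, consensus, evaluation — is correct
and sensitive at realistic effect sizes; it does not certify performance
on any particular real imaging setup.

## Problem sizes and reproducibility

Unit and property tests run on down-scaled plates (300 px dish, ~20
seeds) to keep the suite fast; the oracle checks use 200 random masks
against a flood-fill labeler and an exhaustive sweep of all 2×2 tables
with total ≤ 40 against a binomial-coefficient enumeration. The
end-to-end study — in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` — uses the full default conditions: one training
plate per class and 20 test plates per class for the effect and
zero-effect runs, and 10-fold cross-validation over 40 plates. All
randomness (placement, noise, classifier fitting, fold shuffles) derives
from explicit integer seeds, and the acceptance script threads its
`--seed` argument through every stage.

## Known limitations

* Clumped seeds are counted as one region; heavy clumping biases counts
  and size summaries downward and upward respectively.
* The quartile interpolation rule and the perimeter metric (Moore-step
  polygon length) are documented package choices; other conventions
  (nearest-rank quantiles, crack-boundary perimeters) would shift
  feature values slightly.
* The 13 members are *analogues* of the original classifier families,
  not re-implementations of their exact algorithms; single-member
  accuracies are therefore not comparable, only the consensus behaviour.
* Otsu thresholding assumes a roughly bimodal channel histogram inside
  the ROI; strongly uneven illumination requires a user-supplied fixed
  threshold or ROI.
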