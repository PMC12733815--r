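---
title: "Counting and measuring oysters in top-down photographs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and measuring oysters in top-down photographs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oystermetry)
```

## The problem

On oyster farms, growth is monitored by periodically measuring samples of
*Crassostrea virginica* with a caliper. The measurement is slow and varies
between operators. `oystermetry` automates it from a single top-down
photograph: oysters are spread without touching on a uniform blue
background, with one circular reference object (a soda cap) of known
physical diameter in frame. The package counts the oysters and reports each
one's shell length and width in millimetres, plus per-image means and
standard deviations.

The pipeline has five stages:

1. **Resize** by four in each dimension (area averaging) to keep the
   per-pixel stages cheap, then convert to HSV.
2. **Segmentation** with a hue-based density clustering (a modified
   DBSCAN over pixels): the neighbourhood of a pixel is its 8 adjacent
   pixels, the clustering radius is derived from the image's mean hue, edge
   pixels are excluded, and any group holding more than a tenth of the
   image's pixels is discarded as background.
3. **Noise filtering** with a small multilayer perceptron over size-share
   features, removing shadows, debris and the reference cap.
4. **Calibration and measurement**: the cap is found with a circle Hough
   transform on the luma channel; its known diameter fixes the mm-per-pixel
   scale, and each group is measured by its axis-aligned bounding box.
5. **Refinement** with a 100-tree random forest over geometry features,
   which drops residual noise and resolves *fused* groups (two touching
   oysters in one cluster) by emitting two records with the length halved.

Per-image variability can then be compared against manual measurement with
a paired Wilcoxon signed-rank test (`wilcoxon_paired()`).

## The pixel clustering

Pixels are clustered on the hue channel only. HSV isolates chromaticity
from brightness, and on a blue background the oyster/background contrast is
almost entirely a hue contrast; saturation and value react mostly to
lighting. Distance is circular on the 0–179 hue wheel (the 8-bit
half-degree convention): $d(h_1, h_2) = \min(|h_1 - h_2|,\; 180 - |h_1 -
h_2|)$.

With the neighbourhood fixed to the 8 adjacent pixels, a pixel is a **core**
(label 2) when at least `min_neighbors` of its 8 neighbours are within hue
distance $\varepsilon$; the default `min_neighbors = 8` is the strictest
reading of an 8-neighbour density test. A non-core pixel within
$\varepsilon$ of an adjacent core is a **boundary** pixel (label 1) and
joins that core's group; everything else, and every pixel within
`edge_margin` (default 1) of the border, is an **outlier** (label −1).
Connected cores with their boundaries form one group. Under these
definitions the partition coincides, on images whose hue bands are
separated by more than $\varepsilon$, with plain 8-connected component
labelling of the hue-thresholded mask — except for degenerate 1-px-wide
extremities, which no density-based rule can reach and which are labelled
−1. The test suite checks both this equivalence and exact agreement with an
independent brute-force reimplementation.

The clustering radius adapts to the image:
$\varepsilon = \mathrm{clamp}(k \cdot \overline{H},\; \varepsilon_{\min},
\varepsilon_{\max})$
with $\overline{H}$ the mean hue. Only the *dependence on the average hue*
is inherited from the method's design; the linear-with-clamping form is
this package's interpretation, isolated in `epsilon_policy()` so it can be
swapped. The defaults ($k = 0.12$, floor 8, cap 20) were calibrated once on
the synthetic scenes: a blue background near hue 115 yields
$\varepsilon \approx 12$–13, comfortably above the within-object hue
texture (bounded below 11 by the generator's truncated jitter) and far
below the object/background hue gaps (≥ 20).

Determinism: group ids follow the raster-scan order of each group's first
core pixel, and a boundary pixel adjacent to several groups joins the first
in fixed neighbour order. Both tie-breaks matter only when two groups sit
within $\varepsilon$ of the same pixel, which separable scenes exclude.

## Group classifiers

**Size-share filter (MLP).** Each group is described by three fractions:
its pixel share of the image (`pct_mean`), the population standard
deviation of that share across the image's groups (`pct_std`, an
image-level dispersion attached to every row), and its share of all grouped
pixels (`pct_pixels`, summing to 1 per image). Class 0 is shadow/debris/cap
noise, class 1 an oyster, class 2 an overlapped pair. The network is
3 → 100 ReLU → 3 softmax, trained with full-batch Adam on categorical
cross-entropy for 200 epochs. The training budget is read as 200 full
passes; the learning rate (not part of the method's stated configuration)
is 0.01, chosen so full-batch training converges inside that fixed budget.
Features are standardised with a scaler fitted on the training set and
stored with the model. Class-2 groups are *kept* at this stage — resolving
them is the refinement forest's job.

**Geometry refinement (random forest).** After measurement, each group is
described by its scaled length and width and the scaled bounding-box
corners: values are divided by half the image size and multiplied by 1000.
"Image size" is taken as $\max(H, W)$ so features are comparable across
resolutions, and lengths in millimetres are divided by the half-size
expressed in millimetres — equivalently, everything reduces to pixel ratios,
which is why `rf_features()` takes the mm-per-px scale. The forest has 100
trees with a fixed seed of 42 (part of the method), Gini impurity,
unlimited depth and bootstrap sampling. Class 0 is dropped, class 1 kept,
and each class-2 group is replaced by **two** records with half the length
and unchanged width. The split is bookkeeping on the measurement record, not
a pixel-level re-segmentation: its purpose is to stop fused pairs from
inflating the sample averages, so the two halves conserve the fused length
exactly. Only the length is halved; nothing in the method's description
adjusts the width.

The two classifiers keep separate label vocabularies: a group the MLP calls
class 2 may legitimately be class 1 to the forest once measured.

## Scale calibration

The reference circle is detected on the luma (Y) channel of the YUV image:
Sobel gradients are thresholded into an edge mask (relative cut at a
fraction of the maximum magnitude, with an absolute floor so featureless
images yield no edges), and for each candidate integer radius a unit-mass
ring kernel is correlated with the edge mask by FFT convolution — the
accumulator value is the fraction of the ring covered by edges. The global
maximum wins; below `accumulator_threshold` (default 0.5) the reference is
declared not found and measurement aborts with an actionable error. Because
integer radii quantise the scale (a 0.5 px error on a 7.5 px cap is 7 % of
every measurement), the centre and radius are then refined on the edge
pixels in a 1.5 px annulus, weighted by gradient magnitude; in the test
scenes this brings the scale error below about half a percent.

Two deliberate interpretations: the transform runs on the *resized* image
by default, keeping the mm-per-px scale consistent with the measured
groups (the pre-resize image can be used by configuring `resize = FALSE`);
and the cap is detected before the MLP filter runs, while its pixel group
is trained as class 0 so it never reaches the oyster statistics. The
physical cap diameter is a required configuration value — the method
depends on it and no default is silently assumed.

Measurements use the axis-aligned bounding box: length is the longer side
times mm-per-px, width the shorter. A rotated-box measurement is *not*
provided; see the limitations below.

## The Wilcoxon comparison

`wilcoxon_paired()` reports the classic-package form of the paired
signed-rank test: zero differences are dropped as ties, absolute
differences receive mid-ranks, and the large-sample statistic is
$Z = (W - n(n+1)/4) \,/\, \sqrt{n(n+1)(2n+1)/24 - \sum_t (t^3 - t)/48}$
without continuity correction. Two conventions for $W$ coexist in the
literature: the sum of positive ranks (antisymmetric in the samples,
reported as `z_signed`) and the *smaller* of the two rank sums (always
$Z \le 0$, the convention of the classic statistics packages, reported as
`z`). Both have the same magnitude and p-value. The tie-corrected variance
is always used; with no tied magnitudes the correction term vanishes.
`pairs_from_rank_structure()` rebuilds paired vectors with a prescribed
rank structure, which is how the published rank tables are reproduced in
the acceptance checks.

## The synthetic scene generator

No field imagery ships with the package, so every trainable or testable
claim runs on `generate_scene()`. The generator emulates the documented
acquisition setup — oysters spread on blue foam, photographed from about
40 cm, one soda cap in frame — with the simplest structure sufficient to
exercise every pipeline stage:

* Geometry is sampled **in millimetres** on a 512 mm field and rasterised
  at the requested resolution (default 1024 px, 0.5 mm/px; the pipeline
  then analyses 256 px at 2 mm/px). The same seed re-rendered at another
  scale yields the same physical scene, which is how the scale-equivariance
  property is tested.
* Oysters are ellipses, 60–110 mm long with width 0.45–0.62 of length,
  hue band 12–24 with truncated-Gaussian hue texture (sd 1.5, cut at 2.5
  sd). The background is hue 115 with sd 1.2 jitter; shadows (hue 95) are
  scaled-down offset ellipses; debris specks (hue 55) are small discs; the
  cap (hue 150) is a disc of known diameter, 30 mm by default. Truncating
  the jitter bounds neighbour hue distances strictly below the clustering
  radius, making the scenes hue-separable *by construction* — separability
  is a property of the study conditions, not luck.
* Orientations are near-axis-aligned (jitter sd 3°, cut at 2 sd around 0°
  or 90°): the measurement primitive is the axis-aligned bounding box, which
  under-reads the major axis of a strongly rotated ellipse by construction.
  The generator models the arrangement the acquisition protocol aims for; a
  rotation-robust measurement is out of scope (see limitations).
* Fused pairs are sampled binomially (per-candidate-pair probability 0.25),
  drawn as two ellipses sharing an axis with centres offset 0.7–0.9 of the
  sum of their semi-major axes and near-equal hue, so they merge into one
  cluster whose aspect ratio separates them from singles.
* Placement is rejection packing of clearance discs (semi-major axis plus a
  6 mm gap), placing large objects first and retrying the whole layout on a
  dead end; an infeasible request errors rather than degrading.

Ground truth records every blob's centre, axes (mm and px), orientation,
fused flag, the shadow and debris inventories and the cap circle.
`label_groups()` auto-labels segmented groups: ≥ 70 % of a group's pixels
inside one (1-px-inflated) ellipse ⇒ class 1; inside the union of a fused
pair (both members contributing ≥ 15 %) ⇒ class 2; anything else ⇒ class 0.

What the generator deliberately does **not** emulate: biofouling and dirt
on shells, specular highlights, uneven illumination, perspective and lens
distortion, blur, and oysters whose hue approaches the background. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
self-consistent under the documented acquisition conditions — not that it
is robust to arbitrary field imagery.

## Numerical choices and degenerate inputs

* Hue is integer 0–179; HSV→RGB→HSV round trips are exact to ±1 per
  channel up to chroma ≈ 80 (hue quantisation dominates beyond that); YUV
  round trips are ±1 inside the 8-bit BT.601 gamut.
* Resizing uses area averaging (the standard downsampling interpolant; the
  method's description does not name one).
* A constant-hue image yields the clamped epsilon with a logged note; a
  single measured oyster reports sd 0 with a degenerate flag; an empty
  measurement set reports count 0 with missing (not zero) means; an
  all-ties Wilcoxon input returns a flagged result with `NA` statistics.
* Every stochastic component (scene sampling, MLP initialisation, forest
  bootstrap) is seeded; two runs with the same inputs produce byte-identical
  reports, and the suite asserts it.

## Problem sizes

The shipped checks train on 30 generated scenes (≈ 420 labelled groups,
three classes) and evaluate on 20 held-out clean scenes; segmentation
oracle checks run on 20 scenes at analysis resolution. These sizes were
chosen as the smallest at which the class structure is dense enough for
stable training while the whole suite stays comfortably interactive; the
training scale of the original study (hundreds of images, ~15k groups) is
reproduced in structure, not in volume.

## Known limitations

* The bounding-box measurement under-reads rotated specimens; the method
  inherits this from its measurement primitive. A rotated minimal box would
  remove the bias but is a different method.
* The MLP's three features are all size shares, so it can only separate
  noise from oysters when their size distributions separate; hue- or
  texture-based features are out of scope.
* The fused-pair split halves the length record; it does not re-segment
  pixels, so the two emitted records share one bounding box.
* Circle detection assumes exactly one cap-sized circular object; a second
  circle of similar radius and strong contrast would compete in the
  accumulator.
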