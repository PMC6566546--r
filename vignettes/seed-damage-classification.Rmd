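---
title: "Classifying mechanical processing damage in sugar beet seeds from multispectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mechanical processing damage in sugar beet seeds from multispectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiseed)
```

## The problem

Monogerm sugar beet seeds are polished before pelleting: revolving brushes
rub off the corky pericarp so seeds become uniform in size and shape. The
abrasion can damage the seed coat layers beneath (the outer and inner testa)
and, in severe cases, crush or remove the embryo. Quality control grades this
damage into five classes:

1. partially broken pericarp and/or outer testa, inner testa intact — the
   only grade accepted for pelleting;
2. pericarp and outer testa completely broken, inner testa intact;
3. fractured pericarp/outer testa, inner testa partially crushed, embryo
   sound;
4. partially broken pericarp/outer testa, inner testa damaged, embryo
   intact;
5. severe damage to the embryo, or no embryo at all (empty shells and loose
   pericarp fragments fall here too).

Grading is traditionally done by trained analysts under a microscope.
`msiseed` implements a machine-vision alternative built on 19-band
multispectral reflectance stacks (LED bands at 375–970 nm): segmentation,
extraction of 19 shape/colour/binary variables per seed side, a pixel-level
normalized canonical discriminant transform (nCDA) that highlights exposed
deep tissue, a factor-analytic scoring model, per-class score ranges, and
classification of ventral/dorsal image pairs with confusion-matrix
evaluation.

Because no seed-image data set of this kind is publicly available, the
package ships a synthetic image generator with full per-pixel ground truth;
every stage of the pipeline is developed and tested against it.

## The model, stage by stage

### Pixel transform (nCDA)

Labelled training pixels (19-band reflectance vectors) with class labels
feed a canonical discriminant analysis: the leading solution $w$ of

$$S_B\,w = \lambda\,S_W\,w,$$

where $S_B$ and $S_W$ are the between- and within-class scatter matrices of
the centred pixel vectors. $S_W$ is ridge-regularized as
$S_W + \varepsilon\,\mathrm{tr}(S_W)/19\,I$ with $\varepsilon = 10^{-6}$,
because neighbouring LED bands are strongly correlated. Only the leading
direction is used — one transformed channel is what the damage-highlighting
role needs. "Normalized" is implemented as an affine map of the 1st/99th
percentiles of the projected training pixels onto $[0, 1]$ (percentiles
rather than extremes, for robustness to outlier pixels), clipped outside.
The sign is fixed so the highest-labelled class projects highest: damaged or
deep tissue appears bright. On two-class problems the learned direction
equals the closed-form Fisher direction
$w \propto S_W^{-1}(\mu_2 - \mu_1)$; the test suite verifies this against an
independent direct-solve oracle to $10^{-6}$ relative error.

Training pixels can come from ground-truth tissue maps (synthetic data) or
from any user-supplied labelled masks; background pixels are excluded. The
model stores a *damage threshold* on the normalized scale, used by the
binary features below: the midpoint between the two lowest per-class means
of the transformed values, i.e. pixels brighter than is typical for the
least damage-indicative class count as damaged. In the pipeline this
threshold is recalibrated on the calibration seeds' footprints using their
damage-class labels (`calibrate_damage_threshold()`): the midpoint of the
class-1 and class-2 footprint means. A min/max-midpoint rule was rejected
because the projected position of exposed inner testa between pericarp and
embryo varies with the training set, which made the damaged-area feature
unstable.

### The 19 variables

Only the taxonomy of the original variable set is known — "seed shape,
colour and binary features" — not the exact list, so the package freezes a
defensible reconstruction in one place (`msi_feature_names()`), and the
scoring model accepts any configurable feature set:

* **shape (7)**: area, perimeter, major and minor axis length, length/width
  ratio, circularity $4\pi A/P^2$, compactness (area over convex-hull area);
* **colour (9)**: mean footprint reflectance in the 450, 525, 590, 660, 780
  and 940 nm bands, plus CIELab-style L\*, a\*, b\* computed from
  visible-band means through a fixed nominal sRGB/D65 transform (relative
  values; colorimetric exactness is not required by a relative scoring
  model);
* **binary (3)**: interior hole count of the pre-fill segmentation mask,
  damaged-area fraction (footprint pixels above the nCDA damage threshold),
  damaged-patch count.

Numerical choices that matter here:

* the perimeter is the length of the outer contour polygon after a circular
  moving-average smoothing of the contour vertices (window 7). Raw chain
  codes overestimate length with an orientation-dependent bias; the smoothed
  estimator is accurate to about 1% on discs and rotation-stable to about
  0.1%, which keeps circularity a stable feature;
* hole counting labels enclosed background 8-connected after a one-pixel
  dilation, so a thin oblique fissure — whose rasterized background pixels
  can fragment — counts as one hole; damage patches are counted after a
  one-pixel erosion instead, because patches are separated by thin cracks
  that dilation would bridge;
* the convex hull of pixel centres is dilated to pixel squares
  (shoelace + half hull perimeter + 1) so compactness stays at or below 1
  for convex shapes.

### Scoring (factor analysis)

Calibration features are standardized to zero mean and unit SD; a
principal-component factor extraction runs on their correlation matrix, and
the first factor's loadings are divided by the square root of its eigenvalue
to give *scoring coefficients* — the normalization under which calibration
scores $z^\top v_1/\sqrt{\lambda_1}$ have variance exactly 1 ("united
variance" scores; verified to $10^{-9}$). A single retained factor drives
classification, because the downstream range rule is one-dimensional; the
count of eigenvalues above 1 is kept for diagnostics only. The sign is fixed
so the severest class has the highest mean calibration score.

### Class ranges and pair classification

Each class's provisional score range is mean ± SD of its calibration scores
(sample SD, $n-1$; the severity grading is one-dimensional, so this is the
interval rule used). Classes are ordered by ascending mean score — tied
means abort with an error rather than guessing an order — and overlaps or
gaps between adjacent provisional ranges are corrected by setting each upper
class's minimum to the previous class's maximum. The corrected ranges
therefore tile an interval; the outermost bounds are extended to ±∞ so every
score classifies (a reject-class alternative was considered and left out:
the downstream consequence of an out-of-range score — assignment to the
nearest extreme class — matches how severity extremes behave).

A seed is imaged on both sides. Each side's score maps to the class whose
corrected range contains it, and the seed receives the *more severe* of the
two side classes. The sources do not state how two side classifications
merge; the severity-max rule is this package's interpretation, chosen
because it implements the stated class-1 conservatism — a seed is called
undamaged only if **both** sides look undamaged. It provably admits no more
class-1 false positives than score-averaging (if both sides fall in class
1's interval, so does their mean), and the test suite checks that relation
on simulated runs.

### Evaluation

The evaluation module reproduces the standard report: a 5×5
misclassification table (rows: true class; columns: predicted class),
overall accuracy $100\,\mathrm{correct}/n$, per-class accuracy (diagonal
over true-class row total — the only definition consistent with applying
the overall formula per class), and false-negative / false-positive
percentages of each class expressed relative to *all* evaluated seeds:

$$\mathrm{FN}_c = 100\,\frac{\text{row sum}_c - \text{diag}_c}{n},\qquad
  \mathrm{FP}_c = 100\,\frac{\text{col sum}_c - \text{diag}_c}{n}.$$

Percentages are carried at full precision and rounded to one decimal only
for display. Conservation identities (accuracy% + ΣFN% = 100; ΣFN counts =
ΣFP counts) hold exactly in counts and are asserted over randomized tables.

## What the synthetic generator emulates

`generate_dataset()` renders elliptical seed bodies (10 px/mm; polished
seeds are sieve-graded, so major axes are drawn from a narrow 4.36–4.44 mm
band and both sides of a seed share its physical dimensions) on a dark
background, with per-pixel tissue maps:

* tissue reflectance spectra differ little in the visible region and spread
  apart in the near infrared, with deeper layers
  (pericarp → outer testa → inner testa → embryo) increasingly NIR-bright;
  severely damaged class-5 tissue carries additional NIR brightening;
* class-specific damage geometry: an angular sector of removed pericarp
  exposing deeper tissue, a central crushed-testa patch exposing the embryo,
  a chipped margin bite whose area grades with severity (shape features
  track damage), and thin interior cracks along the seed's long axis whose
  count grades with severity (each leaves one enclosed hole);
* class 5 includes embryo-absent variants (12% of class-5 seeds): almost
  fully exposed, NIR-bright empty shells;
* varieties differ by a fixed per-band reflectance offset (SD 0.3%,
  emulating pericarp colour differences), and seeds are assigned round-robin
  to varieties;
* sensor noise is additive i.i.d. Gaussian on reflectance (default SD 0.5%),
  band-independent — the simplest model consistent with the imaging setup;
* pixels are quantized to the 16-bit storage grid at render time, so writing
  and re-reading a stack is bit-identical.

**The within-grade severity model.** Grading thresholds bound a class's
severity from above, so within a grade the severity distribution is modelled
as left-skewed: a tight log-normal bulk at the class's nominal severity
(scale SD 1.5%), a 15% minority of borderline seeds with clearly milder
damage (severity scaled by 0.70–0.88), and a 15% minority retaining darker
corky pericarp patches (reflectance 1.5–3% lower — the dominant spread
mechanism for class 1, where little else varies). This shape matters for the
classifier: the mean + SD range boundary is scale-free in the within-class
score distribution, so for any *symmetric* noise about 16% of sides per
class would exceed their class's upper bound and be bumped one class up
regardless of how separated the classes are. With the left-skewed model the
milder minority widens each class's calibration SD — lifting the upper
boundary clear of the bulk — while itself landing in the gap below the
class bulk, which the corrected ranges assign to the same class. Damage
*placement* (sector angle, crack and patch positions) is drawn once per
seed and shared by its two sides; only orientation, centring and sensor
noise differ between sides.

**What passing tests do and do not show.** The generator provides exactly
the statistical structure the pipeline assumes: one seed per image, clean
dark background, class-wise separable spectra, and left-skewed within-grade
severity. Real seed images add pose variation, specularities, touching
seeds, texture, and grading noise in the reference labels, none of which is
emulated. Accuracy on the synthetic default (about 90–95% depending on the
seed) therefore demonstrates correct parameter recovery under the model's
own assumptions, not expected field performance; the published real-data
experiment this workflow mirrors reports 82% overall.

## Segmentation choices

Otsu's criterion thresholds the band-mean image — computed on
log-reflectance, because with extensive bright interior damage the plain
criterion can split dark pericarp from bright embryo instead of background
from seed. Foreground components are labelled 8-connected (a BFS labeller
written for this package; coordinates are 0-based, boxes half-open),
components under `min_area = 50` px are discarded as debris, and interior
holes are filled for the footprint while the pre-fill mask is kept for the
binary features. Touching seeds are not separated: the imaging protocol
lays seeds out singly.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → segment → transform → features → train →
classify → evaluate, with every stage boundary written as a plain-text file
(feature table, model files, results table) so any stage can be re-run from
disk bit-for-bit. The default configuration is 60 seeds per class, 18
varieties, 80×80 px images, and a 60/40 calibration/validation split at seed
level (the calibration fraction is configuration, not a constant, since the
sources are ambiguous about the exact counts; at least 2 seeds per class are
always calibrated, and when nothing is left to validate the calibration set
is evaluated on itself). The test suite exercises most properties on 2–4
seeds per class at 60×60 px to stay fast, and the acceptance checks run the
full default once plus a noise grid at 12 seeds per class.

## Known limitations

* The 19-variable set is a reconstruction of an undocumented list; the
  scoring model is agnostic to the exact set, but fitted models are only
  portable across installations via the frozen order.
* The severity-max side rule and the percentile output normalization of the
  transform are documented interpretations of under-specified steps.
* Per-class accuracy of the middle grades is limited by a structural
  property of the mean ± SD range rule (see the severity-model discussion
  above); no amount of class separation removes it for symmetric
  within-class noise.
* Class means that tie, or corrected ranges that collapse (a class's upper
  bound at or below its corrected lower bound), abort with errors rather
  than being resolved silently.
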