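---
title: "Methods: hyperspectral enhancement and classification of corneal epithelium injuries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral enhancement and classification of corneal epithelium injuries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneaHSI)
```

## The problem

Corneal abrasion — partial loss of the epithelium, the cornea's outermost
cell layer — is routinely invisible without fluorescein staining. Unstained
visible/near-infrared hyperspectral cubes of healthy and abraded porcine
corneas have reflectance spectra of very similar shape with only subtle,
band-dependent differences, so the injury cannot be read off any single
band. This package implements a processing chain that turns such cubes into
8-bit images on which the injury is statistically detectable, extracts
first-order histogram features from those images, and classifies eyes as
healthy or injured with a Gaussian-RBF support vector machine. A synthetic
scene generator stands in for the original image set, which is not publicly
deposited; the published 25-eye feature table is packaged as a fixture so
the classification stage can also be run on real measurements.

## Calibration

Raw counts are converted to relative reflectance per pixel and band,

$$R_s(\lambda) = \frac{I_s(\lambda) - I_d(\lambda)}{I_r(\lambda) - I_d(\lambda)} \times 100\,\%,$$

with $I_d$ the dark-current frame and $I_r$ the white (spectralon)
reference. Two numerical policies are ours to fix, because the formula
alone leaves them open:

* **Defective pixels.** Where $I_r - I_d$ is not positive (dead or stuck
  sensor columns) the ratio is undefined; those pixels are flagged
  (`find_defective_pixels()`, default tolerance $10^{-6}$ of the white
  frame's dynamic range) and set to `NA` rather than ±Inf.
* **Clipping.** Specular glare legitimately exceeds the white reference,
  so reflectance is clipped to [0, 150] % by default. This keeps the later
  8-bit quantisation well defined; the bound is configurable and can be
  disabled.

## Region of interest

The cornea is located in a chosen band image by normalised
cross-correlation with a user-supplied template, computed in the frequency
domain (raw correlation and the per-window sums all via zero-padded FFTs).
We use the zero-mean, unit-norm correlation coefficient, so a perfect
(affine) match scores exactly 1; windows with vanishing variance score 0,
and ties at the peak break to the smallest row, then column. The crop is
resampled to 100 × 100 pixels with bilinear interpolation on a
corner-matched grid, which makes a same-size crop the identity and maps
linear ramps onto linear ramps. Rotation- and scale-invariant matching is
out of scope.

## The enhancement chain

`enhance_image()` applies, in order:

1. **Band selection.** The 256-band cube is split into five 50-band
   groups; each group is scored by the mean mutual information between its
   band images and the group-mean image (64 × 64-bin joint histogram,
   natural log), and the highest-scoring group wins, ties to the lowest
   group. On corneal cubes the second window — bands 50–100, roughly the
   green-to-orange 500–630 nm range — is the informative one, and the
   default configuration pins `band_range = c(50, 100)` rather than
   re-running the selection on every cube.
2. **Gamma adjustment** per band: rescale to [0, 1] between the 1st and
   99th percentile (values outside clipped), raise to $\gamma = 0.7$
   (brightening; the raw acquisitions are dark), map back to the band's
   original numeric range. The percentile-clip reading of the otherwise
   undefined "clip pixel level" parameter is an interpretation on our
   part.
3. **Erosion with a non-flat ball SE**, radius 50 px, height 50 gray
   levels: $out(x) = \min_u\, [img(x+u) - b(u)]$ with
   $b(u,v) = h\sqrt{1 - (u^2+v^2)/r^2}$. This removes specular glare
   (saturated blobs much smaller than the ball) while the height profile
   limits how far dark structures spread. Borders are reflect-padded by
   default (configurable to ignore-border). Because the profile is concave,
   each image line can be eroded by a Monge-matrix divide-and-conquer
   solver; the compiled implementation is exact (it equals the brute-force
   minimum bit for bit) and makes the 51-band chain run in about a second.
4. **Laplacian-of-Gaussian filtering**, 9 × 9 kernel, $\sigma = 0.1$,
   sampled from $\frac{x^2+y^2-2\sigma^2}{\sigma^4}
   e^{-(x^2+y^2)/2\sigma^2}$ and then shifted to exact zero sum — the
   continuous operator only integrates to zero over the infinite plane,
   and without the shift flat regions would not map to zero. At
   $\sigma = 0.1$ the sampled kernel is numerically a scaled difference
   between the centre pixel and its 9 × 9 neighbourhood mean, i.e. an
   aggressive high-pass.
5. **Per-cube PCA** over the processed bands, with pixels as observations
   and bands as variables; the population (1/M) covariance is
   eigendecomposed, components with eigenvalues ≤ 1e−12 of the leading one
   are dropped as numerically zero, and at most 10 are retained.
   Eigenvector signs follow the largest-magnitude-loading-positive
   convention so score images are reproducible.
6. **PC difference image**: score image 2 minus score image 1, min–max
   rescaled to 0–255 and rounded. The pair (2, 1) is the default; the
   configuration exposes it because other pairings (for instance the last
   retained component) are plausible and the choice is not canonical. A
   constant difference maps to the all-zero image.

## What the enhancement does — and does not — improve

The chain was designed around contrast-to-noise ratio,
$CNR = |\mu_{roi} - \mu_{bg}| / \sigma_{bg}$ (population SD). Two
empirical facts about our implementation, both reproduced by the test
suite, deserve emphasis:

* On synthetic injured scenes, plain PCA + PC subtraction already yields a
  high interior CNR, and the full chain *lowers* it. The reason is
  structural: a zero-sum high-pass filter (stage 4) removes regional mean
  differences, so any region's mean approaches the background mean and the
  numerator of the interior CNR collapses. The published account reports
  the opposite ordering on its (unavailable) real cubes; with the printed
  parameters and a zero-sum kernel we cannot reproduce that ordering on
  any generator setting, and the corresponding acceptance property is
  deliberately left failing rather than redefining the metric until it
  passes.
* What the chain *does* do is re-encode the injury into the histogram
  shape of the final image. Erosion lets the darker abraded region expand
  into a wide basin (visibly "slightly larger", as expected from a
  morphological minimum), and after PC differencing and 8-bit rescaling,
  injured scenes show markedly lower histogram means and higher skewness
  than healthy ones. Classification on (mean, skewness) of the enhanced
  images separates synthetic cohorts essentially perfectly (pooled CV AUC
  ≥ 0.9 on 40-scene cohorts across 10 master seeds), which is the
  package's end-to-end recovery check.

A related geometric consequence: the final image does not localise the
injury as a sharp contour. Erosion expands the dark abraded basin outward
by roughly the distance at which the ball profile's drop equals the
injury's spectral depth (about 20 px at the defaults — hence the
"slightly larger" look of enhanced injuries), and the high-pass stage
leaves comparable small-scale gradients everywhere, so top-decile
gradient magnitudes scatter across the frame rather than tracing either
the true or the expanded boundary. The injury's footprint in the final
image is a regional darkening, read off the histogram, not an edge map.

## Histogram features

Features are the first-order statistics of the 256-level histogram of the
enhanced image: mean $m_1 = \sum I P(I)$ and central moments
$\mu_k = \sum (I - m_1)^k P(I)$, $k = 2, 3, 4$. The reported skewness and
kurtosis are the *standardised* ratios $\mu_3/\mu_2^{3/2}$ and
$\mu_4/\mu_2^2$ (non-excess: a Gaussian scores 3): the packaged feature
table's magnitudes (skewness 0.27–1.43, kurtosis 4.6–9.7 alongside
standard deviations of 19–29) are only consistent with the standardised
forms, not with raw central moments. Degenerate histograms ($\mu_2 = 0$)
get skewness and kurtosis 0 by convention. The gray-level count N = 256 is
an assumption (8-bit display images); the source does not state it.

## The classifier

`svm_train()` solves the two-class soft-margin dual by sequential minimal
optimisation with maximal-violating-pair working-set selection, to KKT
tolerance 1e−6, recording the iteration count. The GRBF kernel is
$K(x_i,x_j) = \exp(-\|x_i-x_j\|^2 / 2\sigma^2)$; note the width
convention — the common precision form $\exp(-\gamma\|d\|^2)$ corresponds
to $\gamma = 1/(2\sigma^2)$, and the grid's "Sigma" values are taken to be
this $\sigma$. Evaluation is stratified k-fold cross-validation: per-class
shuffle-and-deal fold assignment from a seed (k = n is leave-one-out and
seed-free), out-of-fold decision values pooled, AUC by threshold-sweep
trapezoid (equal to the tie-aware Mann–Whitney statistic), plus the 0/1
label mean squared error, the plain fraction correct, and confusion
counts with injured as the positive class.

Column normalisation to unit Euclidean norm is fitted on the training fold
and applied to its test fold by default, avoiding leakage. The published
procedure normalised "training and testing sets" jointly; `normalize =
"joint"` reproduces that convention and is used for the feature-table
replication, where the whole 25-row table predates any split. Label coding
for the MSE is {0, 1}; solver iteration counts are reported but are
solver-specific and not comparable across implementations.

## Replication of the published classification grid

`replicate_table4()` re-runs the grid over fold seeds. With the spec'd
procedure — joint unit-norm columns, stratified 10-fold CV, pooled AUC —
the (mean, skewness) pair lands around 0.65 at (C = 500, σ = 2.658),
0.74 at (C = 500, σ = 1.658) and 0.63 at (C = 1, σ = 1), far from the
reference values of 1.0, 0.9583 and 0.8333 (the acceptance script
recomputes these numbers on every run). Our solver is not the cause: its
decision values match both a generic QP solver and an independent SVM
implementation to ~1e−5 on this data. Two observations point at a
procedural gap on the other side: every reference accuracy is an integer
multiple of 1/48 = 1/(6 × 8), the pair count of a test split containing 6
of one class and 8 of the other, and every reference error an integer
multiple of 1/11 — consistent with a single train/test partition of the
25 eyes rather than a pooled 10-fold statistic. That partition is not
recoverable, and the (mean, skewness) scatter is visibly interleaved
between classes, so no fold assignment can pool to AUC 1. The replication
targets are therefore reported as computed, without tuning toward the
reference values.

## The synthetic generator

`make_scene()` emulates the acquisition products the calibration stage
expects: a raw cube `counts = dark + (R/100)(white − dark) + noise`, its
dark and white reference frames (the white frame carries a smooth
vignette, which flat-fielding removes exactly), saturated glare disks, and
a ground-truth injury mask. Design choices, fixed once:

* **Base spectrum**: a spline through 8 control points — rising through
  450–600 nm to ~50 % and flat in the NIR — mimicking unstained corneal
  tissue; exact control values are configurable and nothing attempts to
  match absolute published reflectances.
* **Injury offset**: a Gaussian bump centred at 560 nm (width 45 nm), peak
  −4 % reflectance, entirely inside the 503–625 nm selection window and
  small against the base curve (≤ 20 % everywhere) — the two classes are
  deliberately near-identical spectrally. The magnitude is a free
  parameter of the study design; −4 % against ~1.5 % per-pixel noise makes
  single-band detection noisy but multi-band detection reliable, which is
  the regime the chain is meant for.
* **Injury geometry**: one connected blob covering ≈ 10 % of the frame
  with a smooth, irregular boundary (a jittered disk, Gaussian-blurred and
  thresholded at 0.5). The offset is applied binarily inside the mask so
  that noise-free scenes recover it *exactly* — the smoothness lives in
  the mask's shape, not in a partial-volume edge.
* **Noise**: i.i.d. Gaussian, 1.5 % reflectance per pixel and band.
  Healthy tissue is spatially flat apart from noise; this keeps the
  noise-free inversion identity exact at every pixel, at the cost of not
  modelling corneal curvature shading, spatially correlated texture,
  stain fluorescence, or specular geometry. Passing tests therefore
  certify the pipeline's mechanics and statistical behaviour on this
  idealisation, not clinical performance on real corneas.
* **Seeds**: one master seed per cohort; child seeds are master + index,
  so any scene regenerates independently; identical seeds give
  bit-identical scenes.

## Problem sizes and runtime choices

The test suite exercises: full-size 100 × 100 × 256 scenes for the
acceptance properties (50 injured scenes for the CNR comparison; ten
40-scene cohorts, 18 healthy / 22 injured, for end-to-end recovery);
16-band scenes and a 10-px ball for the fast unit-level pipeline checks;
12 × 12 images against the brute-force erosion oracle; 200 random sets
for the AUC pair-counting identity; and ≤ 6-point problems against the
interior-point QP oracle. These sizes are the package's own balance of
statistical power against a desk-scale run.

## Known limitations

* The published CNR figures for individual eyes are not reproducible
  without the original cubes, and the CNR-improvement ordering does not
  hold under a zero-sum LoG (discussed above).
* The template for ROI matching is an input; nothing is said about how to
  build one, and matching is translation-only.
* No second-order (co-occurrence) texture features, no multi-class
  support, no probability calibration, and no deep-feature (CNN) branch.
* ENVI I/O covers the BSQ/little-endian float subset this package writes,
  not the full format zoo.
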