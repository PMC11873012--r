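---
title: "Measuring the computational depth of rodent object vision: methods"
author: "ratvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the computational depth of rodent object vision: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratvision)
```

## The question the package operationalizes

When a rat discriminates two visual objects across changes in size, pose
and position, how much computation does that behavior actually demand?
One productive way to pose the question is to feed the same stimuli to a
deep feedforward network, train a linear classifier on the activations of
each layer, and ask at which depth the pattern of classification accuracy
across stimulus conditions — not its absolute level — best matches the
animal's. A parallel comparison of *visual strategies* asks whether the
image regions that drive choices (classification images) are anchored to
the object or to the screen. This package implements that machinery
end to end on synthetic stimuli and simulated observers, so every stage
is testable without animal data: a rendering and augmentation front end
matched to rat acuity and head movement, a simulated
contrast-sensitivity observer used to calibrate the front end, untrained
network architectures with parameter accounting, per-layer linear
readouts, two classification-image estimators with permutation tests,
and overlap metrics that dissociate object-centered from screen-centered
strategies.

Images are plain numeric matrices in [0, 1]; the pixel-to-degree
conversion runs through a `ViewingGeometry` object whose defaults encode
the behavioral rig the analyses assume: a 48 x 27 cm display viewed at
30 cm, rendered at 224 x 224 px spanning roughly 96 degrees of visual
angle (ppd = 224/96 ≈ 2.33). That printed pixel-angle convention is
adopted as is, although it is slightly more generous than the
2·atan(24/30) ≈ 77 degrees implied by the screen size and distance; all
degree-based quantities (bubble sizes, grating frequencies, object
sizes) use the printed factor.

## Stimuli and simulated observers

Objects are procedural "lobed" models: capsule-shaped 3D segments
joined at a common origin, filled at intensity 1 on a background of
exactly 0 (the rig's object/background polarity is not documented; white
on black is assumed). Two canonical models are fixed: a 3-lobed tripod
and a 4-lobed cross. A view is parameterized by size (degrees of
bounding extent), azimuth (in-depth rotation, realized as a true 3D
rotation about the vertical axis followed by orthographic projection, so
foreshortening is genuine), in-plane rotation, horizontal shift, and a
regular/outline style flag.

Two rendering conventions matter downstream:

* **Size convention.** The scale is set so that the azimuth-projected
  bounding extent (including lobe thickness) spans `size_deg * ppd`
  pixels. The scale is fixed *before* the in-plane rotation — rolling an
  object does not change its physical size — and the object's origin
  (the lobe junction) is anchored at the image center. Every view
  transform is therefore an affine map about the image center, which is
  what lets `alignMap()` invert it exactly.
* **Outlines.** The outline style keeps only the boundary band of the
  filled region: foreground pixels with background within Chebyshev
  distance 2 px (configurable; the band width is not documented in the
  source experiments).

Random structural variants perturb each lobe independently: a signed
in-plane direction jitter uniform on ±20 degrees and a relative length
jitter uniform on ±20% by default. These defaults are the package's
definition of "random variants of the learned object": large enough that
most variants are visibly different, small enough that the family stays
tripod-like.

Three simulated observers generate trial-by-trial labels. A *template
matcher* picks the class whose stored template has the larger dot
product, with a lapse: with probability λ the response is replaced by a
fair coin, the standard psychophysics convention for the large lapse
rates of rodent decisions, which cap achievable accuracy without
reflecting perceptual failure. A *planted-feature responder* answers
correctly exactly when the mean occlusion-mask transparency over a fixed
pixel set exceeds a visibility threshold — a ground-truth generator for
classification-image recovery tests. The *ideal observer* stores every
(object, view) template and classifies by maximum dot product
(unnormalized; ties break to the lowest template index). The dot product
is left unnormalized because the stimulus set equates template energy
closely and the original formulation specifies a plain dot product.

## Augmentation front end

Head-pose variability is converted into image transformations. Pitch,
roll and yaw are drawn uniformly over measured full spans of 60, 35 and
20 degrees. Roll maps directly to in-plane rotation (±17.5 degrees). A
signed yaw (pitch) of θ deflects the gaze across the screen by
`d·tan(θ)` cm; over a full span Θ this sweeps `2d·tan(Θ/2)` cm, and
dividing by the screen extent gives translations as fractions of the
image. The extreme draws land exactly on
`displacementFraction(angularDisplacement(span, d), screen)` — 0.110 of
the width for yaw and 0.641 of the height for pitch at the default
geometry.

The acuity front end applies a separable Gaussian blur (SD in px,
reflect padding) followed by i.i.d. additive Gaussian noise and clipping
to [0, 1]. Blur precedes noise by design: blur stands in for the eye's
optics, noise for downstream neural variability; the source description
does not fix the order. Affine warps use bilinear interpolation about
the geometric image center with zero fill.

## The simulated CSF observer and the blur/noise calibration

The blur and noise levels are not free knobs: they are calibrated so
that a simple simulated observer reproduces a target contrast
sensitivity function (CSF). The observer performs a yes/no grating
detection task: a linear SVM (C = 1) is trained on patch-contrast
features — the population SD of pixel intensities in non-overlapping
28 x 28 px patches, anchored at the top-left of the largest centered
multiple — to discriminate blurred and noisy sine gratings (random
orientation and phase, contrast drawn uniformly over the 12-point
log-spaced test grid in [0.005, 1]) from noisy uniform mid-gray images.

One deliberate addition: the fitted SVM is given an explicit *decision
criterion*, calibrated on fresh signal-free trials so that the false
alarm rate is 5%. Without it, an unbiased classifier facing
indiscriminable gratings (e.g. frequencies far above the blur cutoff)
answers "grating" on about half the trials, and the threshold rule below
then assigns spuriously high sensitivity. With the criterion, the
psychometric baseline sits at the false-alarm-matched level and rises
toward 1 only with real signal — the standard signal-detection reading
of a yes/no task.

The contrast threshold ξ(ν) is the first upward crossing of p = 0.5,
interpolated linearly in log contrast; a curve that starts above 0.5
returns the lowest tested contrast, one that never reaches 0.5 returns
ξ = ∞ (sensitivity 0). Sensitivity is σ(ν) = 1/ξ(ν). The frequency grid
is 8 log-spaced points (0.2 dex) at 0.04, 0.063, 0.1, 0.158, 0.251,
0.398, 0.631 and 1.0 cycles/deg — chosen so the grid contains exactly
the three frequencies at which the target curve is anchored.

`fitCSF()` grid-searches (σ_blur, σ_noise, patch size), minimizing the
L1 distance Σ_ν |σ_sim − σ_target|. The target for calibration is
`ratCSFStandin()`: a smooth unimodal curve built from the published
descriptors of the Long-Evans rat CSF — peak at 0.1 cycles/deg, zero
sensitivity at 0.04 and at 1.0 cycles/deg — implemented as two
half-parabolas in log frequency with a configurable peak sensitivity
(default 20; the measured curve's numeric values are not published).

Because the simulated observer's curve has a broad, flat top, the peak
frequency is read with `csfPeakFrequency()`, the vertex of a truncated
log-parabola (independent half-widths) fitted to the measured curve —
the standard parametric CSF descriptor — rather than the grid argmax,
which for a flat-topped noisy curve merely reports sampling noise.

Problem sizes: CSF fitting runs on a 112 x 112 px display at the
standard ppd (a 48-degree aperture), with 500 samples per class, 15
psychometric trials per contrast and 3 repetitions per grid cell, over a
5 x 5 blur/noise grid; the winning cell is then re-measured with 1500
samples per class and 50 trials per contrast. These sizes give
thresholds stable to a few percent while keeping a full calibration in
the minutes range on one CPU.

## Networks, readouts and accuracy-pattern comparison

Two architectures are provided. `buildVGG16()` instantiates the standard
16-weight-layer convolutional layout (13 3x3 convolutions in five
max-pooled blocks, then 4096/4096/1000 fully connected) with seeded
fan-in-uniform random weights; pretrained weights are deliberately not
bundled, and every analysis here runs on the untrained network. The
spatial input size is configurable (any multiple of 32): parameter
accounting always uses the standard 224 configuration — 138 million
parameters — while activation probing can run at 64 x 64 with the full
96-degree field mapped onto the smaller raster, trading acuity for
tractability. `buildMLPTable1()` is the depth- and parameter-matched
fully connected control: 16 affine stages sized
50176 → 2150 → 2048(×4) → 1024(×10) → 1000, whose per-stage parameter
counts round to 108, 4, 4, 4, 4, 2, 1(×9), 1 million — 136 million by
the rounded column. Activations are always recorded *before* the ReLU
of the probed layer (including the final layer, where pre-activation is
used), and grayscale stimuli are replicated across the three input
channels of the convolutional network.

Readouts follow a fixed protocol: sample a unit subpopulation (uniform
without replacement, capped at the layer size), z-score each unit on the
training stimuli (population SD; zero-variance units dropped with a
message), train a linear SVM (C = 1), and evaluate per condition cell.
Two comparison metrics relate a readout's accuracy pattern to a
reference observer: the L1 distance, defined as the *mean* absolute
cell difference so values are comparable across stimulus sets of
different size (the source is ambiguous between sum and mean), and the
Pearson correlation over cells, which ignores the overall accuracy
scale — the appropriate comparison when lapses cap one observer's
ceiling. `extremaHistogram()` summarizes where each of the runs × scales
curves attains its extremum, with ties broken toward the shallower
layer.

## Classification images and their permutation tests

The *bubbles* estimator occludes a view with masks made of `N_b = 40`
Gaussian transparency apertures whose centers fall uniformly in the
centered square spanning 70% of the image; the aperture sum is clipped
at 1 (overlapping bubbles cannot exceed full transparency — the source
is silent, and clipping keeps masks interpretable as alpha values). The
"2 degrees of visual angle" bubble size is interpreted as the full width
at half maximum, giving σ = 2·ppd/2.355 px; the FWHM reading is a
documented choice (σ-vs-diameter is unstated in the source) and is
configurable. Masking applies `p* = p·m` against the black background
and happens *before* augmentation. With correctness labels `l_μ` over
`N_m = 3000` masks, the saliency map is
`S_ij = Σ_μ m^μ_ij l_μ / Σ_μ m^μ_ij`; never-covered pixels are NA and
excluded from all statistics. Significance uses 1000 label permutations
and one-tailed per-pixel tests at p < 0.05 against interpolated null
quantiles, with no multiplicity correction — deliberately matching the
source procedure, which means about 5% of covered pixels are flagged per
tail even under the null. When salient regions must be compared across
observers at matched sizes, `areaMatchedThreshold()` adjusts the
threshold by bisection until the salient area hits a target; its
Gaussian-null mode (per-pixel normal fit to the permutation null) is
provided because empirical quantiles saturate at the permutation
maximum and cannot isolate regions smaller than the strong-signal halo.

The *structural-variant* estimator needs no masks: over random variants
`T^μ` with binary choices `r_μ`, the map is the difference of
conditional means `S = E[T | r=1] − E[T | r=0]`. Its significance test
follows the source exactly: 100 choice permutations, a one-dimensional
Gaussian fitted per pixel to smooth the null, one-tailed tests at
p < 0.01; zero-variance pixels are marked non-significant and counted.

## Invariance metrics

Overlap of two salient regions is intersection over union (the "30% of
the union" phrasing fixes the denominator), defined as 0 when both
regions are empty. The *raw* overlap works in screen coordinates; the
*aligned* overlap first inverts each view's transformation — inverse
horizontal shift, inverse in-plane rotation and inverse size scaling
about the image center, all exact for this renderer — plus an
approximate azimuth inversion by horizontal re-expansion by
1/cos(azimuth) (the true inverse of an orthographic rotation is not a
2D affine; the correction is documented and can be disabled, and is
undefined at |azimuth| ≥ 90 degrees). Boolean masks are resampled
nearest-neighbor so membership stays crisp. A large aligned overlap
with a small raw overlap is the signature of an object-centered
strategy; the package's tests reproduce that dissociation with two
constructed observers over in-plane rotated views — one whose salient
region rides a lobe tip, one locked to a central screen window.

For the spontaneous-generalization paradigm, `choiceFraction()` and
`outlineConsistency()` quantify how often random variants are classified
as the target and how consistent those choices are between regular and
outline renderings, scoring the outline choices against the regular
choices as ground truth (accuracy = TN + TP).

## Experiment pipelines

`runTransformMatrix()`, `runOcclusion()` and `runVariants()` wire the
pieces into the three study designs: on-cross training / full-matrix
evaluation over a size × azimuth grid with L1/Pearson depth profiles and
extrema histograms; mixed unoccluded/occluded training (50% each — the
regime that avoids degenerate occluded-test behavior, which the report
flags when one object's occluded accuracy collapses below 10% while the
other's exceeds 90%) with per-view bubbles maps and a pixel baseline;
and target-vs-distractor training probed with regular and outline
variants in a pure generalization setting. Train and test stimuli always
receive independent augmentation draws. The `experimentProfile()`
helper bundles the published counts ("paper": 5000 training images,
3000 masks per view, 5 runs, five population scales from 10^3 to 10^5)
and a reduced "desk" profile for exploration; the pipelines accept any
activation provider, so the same orchestration runs on a toy ladder
network, the untrained convolutional network, or simulated responders.

## What the synthetic data do and do not establish

The generator reproduces the *structure* of the source experiments —
transformation grids, occlusion statistics, variant families, lapse-
limited observers — but not rat vision: passing tests demonstrate that
the estimators recover planted ground truth under the stated conditions
(calibrated false-positive rates, recovery of planted features and
hidden templates, correct dissociation of constructed strategies), not
that any biological claim holds. Quantities that depend on the deposited
rat data — per-layer accuracy values with pretrained weights, the
published overlap values, peak correlations around 0.8 — are outside
what synthetic stand-ins can reproduce; the loaders in the I/O module
accept such reference data when available. Known limitations: the
renderer's azimuth inversion is approximate; the 224↔96-degree mapping
is internally inconsistent with the rig trigonometry but adopted from
the source; the CSF observer's low-frequency roll-off is mild because a
12-degree patch still sees substantial intensity variation at 0.04
cycles/deg, so the fitted curve's top is broad; and untrained networks
probed at reduced raster sizes lose fine acuity relative to the 224
configuration.
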