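# ratvision

Tools for asking how much computational depth a visual
object-discrimination task demands, built around the comparison of rodent
psychophysics with layer-wise linear readouts of deep feedforward
networks.

Rats discriminate objects across changes in size, in-depth rotation,
position and in-plane rotation, tolerate heavy occlusion, and generalize
to outline versions of learned shapes. Whether that reflects genuinely
deep processing or low-level shortcuts can be probed by feeding the same
stimuli to a convolutional network, training a linear support vector
machine (SVM) on the activations of each layer *l*, and asking at which
depth the pattern of accuracy across stimulus conditions best matches the
animal's — via the mean absolute difference (L1) and the Pearson
correlation of the two accuracy patterns. A second axis of comparison
targets the *visual strategy*: classification images estimated either
with the bubbles method,

    S_ij = ( Σ_μ m_ij^μ l_μ ) / ( Σ_μ |m_ij^μ| ),

where `m^μ` are random Gaussian-aperture occlusion masks and `l_μ` binary
correctness labels over N_m trials, or with random structural variants
`T^μ` of a learned object and spontaneous choices `r_μ`,

    S_ij = E[T_ij^μ | r_μ = 1] − E[T_ij^μ | r_μ = 0],

each with one-tailed per-pixel permutation tests. Raw vs aligned
intersection-over-union of the significant salient regions across views
then dissociates screen-centered from object-centered strategies.

The package implements the full pipeline on procedural stimuli and
simulated observers, so every stage is testable without animal data:

* **Stimuli** — lobed 3D object models (a canonical "tripod" and
  "cross"), rendered with true azimuth foreshortening, size/rotation/
  shift control, outline reduction, and seeded random structural
  variants; simulated observers (template matcher with lapses,
  planted-feature responder, ideal observer).
* **Augmentation** — head-pose jitter converted to affine image
  transformations via `Δ = 2·d·tan(θ/2)`, plus a Gaussian blur + noise
  front end.
* **CSF calibration** — a simulated grating-detection observer (linear
  SVM on patch-contrast features) whose psychometric thresholds yield a
  contrast sensitivity function; `fitCSF()` grid-searches blur and noise
  against a target CSF built from the published rat descriptors (peak at
  0.1 cycles/deg, zeros at 0.04 and 1.0).
* **Networks** — untrained VGG-16-layout convolutional network and the
  depth- and parameter-matched 16-stage MLP, with exact parameter
  accounting and pre-ReLU activation extraction.
* **Readouts & metrics** — z-scored unit subsamples, linear SVM
  readouts, per-condition accuracy matrices, L1/Pearson pattern
  comparisons, extrema histograms, pixel baseline.
* **Saliency & invariance** — both classification-image estimators,
  permutation significance, area-matched thresholds, raw/aligned
  overlap, outline-consistency confusion matrices.
* **Experiments** — `runTransformMatrix()`, `runOcclusion()`,
  `runVariants()` orchestrate the three study designs with reproducible
  seeds and a report/manifest writer.

## Worked example

Calibrate the acuity front end at desk scale and read off the fitted
observer's peak spatial frequency:

```r
library(ratvision)
set.seed(1)

geom   <- viewingGeometry(resW = 112L, resH = 112L)  # 48 deg aperture
target <- ratCSFStandin()                            # peak 20 at 0.1 cyc/deg

fit <- fitCSF(target,
              sigmaBlurGrid  = c(0.5, 1, 1.5, 2, 3),
              sigmaNoiseGrid = c(0.02, 0.05, 0.1, 0.2, 0.4),
              patchSizes = 28L, geom = geom,
              nPerClass = 500L, nTrials = 15L)
fit
#> CSFFitResult: sigmaBlur=1 px, sigmaNoise=0.1, patch=28, L1=40

final <- computeCSF(noiseBlurParams(fit@sigmaBlur, fit@sigmaNoise),
                    fit@patchSize, geom = geom,
                    nPerClass = 1000L, nTrials = 40L)
round(sensitivity(final), 1)
#> [1] 17.7 24.5 24.5 23.5 17.2 13.3  6.0  0.0
csfPeakFrequency(final)
#> [1] 0.095
```

The fitted blur of about 1 px and noise SD of 0.1 reproduce a band-pass
sensitivity curve: contrast sensitivity near 24 (threshold ≈ 4%
contrast) around 0.1 cycles/deg, falling to zero at 1 cycle/deg — a
functional stand-in for the acuity limit the front end is meant to
impose. `csfPeakFrequency()` reads the peak from a fitted truncated
log-parabola, the standard smooth CSF descriptor.

Downstream, the same front end feeds the readout analyses, e.g. probing
an untrained convolutional network:

```r
net  <- buildVGG16(inputSize = 64L, seed = 3)
acts <- extractActivations(net, layerId = 13L, images)  # pre-ReLU
```

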