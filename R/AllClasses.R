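#' Viewing geometry of the behavioral rig
#'
#' Captures the monitor size, viewing distance and pixel resolution of the
#' stimulus display, plus the pixels-per-degree factor used to convert
#' between visual angle and image pixels. Defaults reproduce the rig the
#' analyses assume: a 48 cm x 27 cm monitor viewed at 30 cm, rendered at
#' 224 x 224 pixels spanning ~96 degrees, i.e. ppd = 224/96.
#'
#' @slot d viewing distance in cm.
#' @slot screenW,screenH physical screen size in cm.
#' @slot resW,resH display resolution in pixels.
#' @slot ppd pixels per degree of visual angle.
#' @aliases ViewingGeometry
#' @exportClass ViewingGeometry
setClass("ViewingGeometry",
  representation(d = "numeric", screenW = "numeric", screenH = "numeric",
                 resW = "integer", resH = "integer", ppd = "numeric"),
  validity = function(object) {
    v <- c(object@d, object@screenW, object@screenH,
           object@resW, object@resH, object@ppd)
    if (any(!is.finite(v)) || any(v <= 0)) return("all fields must be > 0")
    TRUE
  })

#' @param d,screenW,screenH,resW,resH,ppd see slots.
#' @return a `ViewingGeometry` object.
#' @rdname ViewingGeometry-class
#' @export
viewingGeometry <- function(d = 30, screenW = 48, screenH = 27,
                            resW = 224L, resH = 224L, ppd = 224 / 96) {
  new("ViewingGeometry", d = d, screenW = screenW, screenH = screenH,
      resW = as.integer(resW), resH = as.integer(resH), ppd = ppd)
}

#' Head-pose variability ranges
#'
#' Full angular spans (degrees) of pitch, roll and yaw head rotations
#' observed during unrestrained stimulus viewing. Defaults are the measured
#' spans 60, 35 and 20 degrees.
#'
#' @slot pitchSpan,rollSpan,yawSpan full spans in degrees (not half-widths).
#' @aliases HeadPoseRanges
#' @exportClass HeadPoseRanges
setClass("HeadPoseRanges",
  representation(pitchSpan = "numeric", rollSpan = "numeric",
                 yawSpan = "numeric"),
  validity = function(object) {
    v <- c(object@pitchSpan, object@rollSpan, object@yawSpan)
    if (any(!is.finite(v)) || any(v < 0)) return("spans must be >= 0")
    TRUE
  })

#' @param pitchSpan,rollSpan,yawSpan see slots.
#' @rdname HeadPoseRanges-class
#' @export
headPoseRanges <- function(pitchSpan = 60, rollSpan = 35, yawSpan = 20) {
  new("HeadPoseRanges", pitchSpan = pitchSpan, rollSpan = rollSpan,
      yawSpan = yawSpan)
}

#' Blur and noise front-end parameters
#'
#' @slot sigmaBlur Gaussian blur SD in pixels.
#' @slot sigmaNoise additive Gaussian noise SD in intensity units.
#' @aliases NoiseBlurParams
#' @exportClass NoiseBlurParams
setClass("NoiseBlurParams",
  representation(sigmaBlur = "numeric", sigmaNoise = "numeric"),
  validity = function(object) {
    if (object@sigmaBlur < 0 || object@sigmaNoise < 0)
      return("sigmaBlur and sigmaNoise must be >= 0")
    TRUE
  })

#' @param sigmaBlur,sigmaNoise see slots.
#' @rdname NoiseBlurParams-class
#' @export
noiseBlurParams <- function(sigmaBlur = 0, sigmaNoise = 0) {
  new("NoiseBlurParams", sigmaBlur = sigmaBlur, sigmaNoise = sigmaNoise)
}

#' One draw of the head-pose augmentation
#'
#' An in-plane rotation plus x/y translations expressed as fractions of the
#' image size, as produced by [sampleHeadPose()].
#'
#' @slot alphaDeg in-plane rotation (degrees).
#' @slot xFrac,yFrac translations as fractions of image width/height.
#' @aliases AugmentationSample
#' @exportClass AugmentationSample
setClass("AugmentationSample",
  representation(alphaDeg = "numeric", xFrac = "numeric", yFrac = "numeric"))

#' @param alphaDeg,xFrac,yFrac see slots.
#' @rdname AugmentationSample-class
#' @export
augmentationSample <- function(alphaDeg = 0, xFrac = 0, yFrac = 0) {
  new("AugmentationSample", alphaDeg = alphaDeg, xFrac = xFrac,
      yFrac = yFrac)
}

#' Full augmentation configuration
#'
#' Bundles head-pose ranges, viewing geometry and the blur/noise front end
#' for [augment()].
#'
#' @slot ranges a [HeadPoseRanges-class].
#' @slot geom a [ViewingGeometry-class].
#' @slot noiseBlur a [NoiseBlurParams-class].
#' @aliases AugmentationConfig
#' @exportClass AugmentationConfig
setClass("AugmentationConfig",
  representation(ranges = "HeadPoseRanges", geom = "ViewingGeometry",
                 noiseBlur = "NoiseBlurParams"))

#' @param ranges,geom,noiseBlur see slots.
#' @rdname AugmentationConfig-class
#' @export
augmentationConfig <- function(ranges = headPoseRanges(),
                               geom = viewingGeometry(),
                               noiseBlur = noiseBlurParams()) {
  new("AugmentationConfig", ranges = ranges, geom = geom,
      noiseBlur = noiseBlur)
}

#' Lobed 3D object model
#'
#' A simple procedural object: a set of capsule-shaped lobes (3D segments
#' with a thickness) attached to a common center, filled at a constant
#' intensity. Lobes are lists with fields `start`, `end` (length-3 numeric,
#' object units; y points up, z toward the viewer) and `thickness`.
#'
#' @slot objectId label.
#' @slot lobes list of lobes (at least 2).
#' @slot intensity fill level in \[0, 1\].
#' @aliases ObjectModel
#' @exportClass ObjectModel
setClass("ObjectModel",
  representation(objectId = "character", lobes = "list",
                 intensity = "numeric"),
  validity = function(object) {
    if (length(object@lobes) < 2) return("need at least 2 lobes")
    for (lb in object@lobes) {
      if (!all(c("start", "end", "thickness") %in% names(lb)))
        return("each lobe needs start, end, thickness")
      if (length(lb$start) != 3 || length(lb$end) != 3)
        return("lobe endpoints must be 3D")
      if (lb$thickness <= 0) return("lobe thickness must be > 0")
    }
    if (object@intensity < 0 || object@intensity > 1)
      return("intensity must lie in [0, 1]")
    TRUE
  })

#' @param objectId,lobes,intensity see slots.
#' @rdname ObjectModel-class
#' @export
objectModel <- function(objectId, lobes, intensity = 1) {
  new("ObjectModel", objectId = objectId, lobes = lobes,
      intensity = intensity)
}

#' View parameters of a rendered stimulus
#'
#' @slot sizeDeg visual angle of the object's bounding extent (degrees).
#' @slot azimuthDeg in-depth rotation about the vertical axis (degrees).
#' @slot inplaneDeg rotation in the image plane (degrees).
#' @slot hshiftDeg horizontal offset (degrees).
#' @slot style `"regular"` (filled) or `"outline"`.
#' @aliases ViewParams
#' @exportClass ViewParams
setClass("ViewParams",
  representation(sizeDeg = "numeric", azimuthDeg = "numeric",
                 inplaneDeg = "numeric", hshiftDeg = "numeric",
                 style = "character"),
  validity = function(object) {
    if (object@sizeDeg <= 0) return("sizeDeg must be > 0")
    if (!object@style %in% c("regular", "outline"))
      return("style must be 'regular' or 'outline'")
    TRUE
  })

#' @param sizeDeg,azimuthDeg,inplaneDeg,hshiftDeg,style see slots.
#' @rdname ViewParams-class
#' @export
viewParams <- function(sizeDeg = 35, azimuthDeg = 0, inplaneDeg = 0,
                       hshiftDeg = 0, style = "regular") {
  new("ViewParams", sizeDeg = sizeDeg, azimuthDeg = azimuthDeg,
      inplaneDeg = inplaneDeg, hshiftDeg = hshiftDeg, style = style)
}

#' Specification of a random structural variant
#'
#' Controls the per-lobe direction and length jitter used by
#' [makeStructuralVariant()] to produce random shape variations of a target
#' object.
#'
#' @slot angleJitterDeg max per-lobe direction perturbation (degrees).
#' @slot lengthJitter max relative lobe-length perturbation.
#' @slot seed RNG seed.
#' @aliases StructuralVariantSpec
#' @exportClass StructuralVariantSpec
setClass("StructuralVariantSpec",
  representation(angleJitterDeg = "numeric", lengthJitter = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@angleJitterDeg < 0 || object@lengthJitter < 0)
      return("jitters must be >= 0")
    TRUE
  })

#' @param angleJitterDeg,lengthJitter,seed see slots.
#' @rdname StructuralVariantSpec-class
#' @export
structuralVariantSpec <- function(angleJitterDeg = 20, lengthJitter = 0.2,
                                  seed = 1L) {
  new("StructuralVariantSpec", angleJitterDeg = angleJitterDeg,
      lengthJitter = lengthJitter, seed = as.integer(seed))
}

#' Simulated observer specification
#'
#' Three observer kinds produce trial-by-trial binary labels from stimuli:
#' `"template"` (argmax dot product against two stored templates, lapsing
#' to a fair coin with probability `lapseRate`), `"planted_feature"`
#' (responds correct iff the mean occlusion-mask value over a planted pixel
#' set exceeds a visibility threshold) and `"ideal_observer"` (template
#' matching over a full template store, see [IdealObserver-class]).
#'
#' @slot kind observer kind.
#' @slot lapseRate probability of a uniformly random choice.
#' @slot params kind-specific parameter list (see [simulateResponses()]).
#' @aliases ResponderSpec
#' @exportClass ResponderSpec
setClass("ResponderSpec",
  representation(kind = "character", lapseRate = "numeric",
                 params = "list"),
  validity = function(object) {
    if (!object@kind %in% c("template", "planted_feature", "ideal_observer"))
      return("unknown responder kind")
    if (object@lapseRate < 0 || object@lapseRate > 1)
      return("lapseRate must lie in [0, 1]")
    TRUE
  })

#' @param kind,lapseRate,params see slots.
#' @rdname ResponderSpec-class
#' @export
responderSpec <- function(kind, lapseRate = 0, params = list()) {
  new("ResponderSpec", kind = kind, lapseRate = lapseRate, params = params)
}

#' Psychometric detection curve
#'
#' Detection probability (with SD over repetitions) as a function of
#' grating contrast, at one spatial frequency.
#'
#' @slot contrasts ascending contrast grid.
#' @slot pDetect mean detection probability per contrast.
#' @slot pSD SD of the detection probability over repetitions.
#' @aliases PsychometricCurve
#' @exportClass PsychometricCurve
setClass("PsychometricCurve",
  representation(contrasts = "numeric", pDetect = "numeric",
                 pSD = "numeric"),
  validity = function(object) {
    if (length(object@contrasts) != length(object@pDetect))
      return("contrasts and pDetect must have equal length")
    if (is.unsorted(object@contrasts, strictly = TRUE))
      return("contrasts must be strictly ascending")
    if (any(object@pDetect < 0 | object@pDetect > 1))
      return("probabilities must lie in [0, 1]")
    TRUE
  })

#' @param contrasts,pDetect,pSD see slots.
#' @rdname PsychometricCurve-class
#' @export
psychometricCurve <- function(contrasts, pDetect, pSD = rep(0, length(pDetect))) {
  new("PsychometricCurve", contrasts = contrasts, pDetect = pDetect,
      pSD = pSD)
}

#' Contrast sensitivity function curve
#'
#' Sensitivity (reciprocal of the contrast detection threshold) per spatial
#' frequency.
#'
#' @slot nus spatial frequency grid (cycles/deg).
#' @slot sensitivity sensitivity values (>= 0; 0 encodes an unreachable
#'   threshold).
#' @aliases CSFCurve
#' @exportClass CSFCurve
setClass("CSFCurve",
  representation(nus = "numeric", sensitivity = "numeric"),
  validity = function(object) {
    if (length(object@nus) != length(object@sensitivity))
      return("nus and sensitivity must have equal length")
    if (any(object@sensitivity < 0)) return("sensitivity must be >= 0")
    if (any(object@nus <= 0)) return("spatial frequencies must be > 0")
    TRUE
  })

#' @param nus,sensitivity see slots.
#' @rdname CSFCurve-class
#' @export
csfCurve <- function(nus, sensitivity) {
  new("CSFCurve", nus = nus, sensitivity = sensitivity)
}

#' Result of the blur/noise grid search against a target CSF
#'
#' @slot sigmaBlur,sigmaNoise,patchSize best-fit parameters.
#' @slot l1 L1 distance at the optimum.
#' @slot landscape L1 distance over the full grid, an array with dims
#'   (blur, noise, patch).
#' @slot grid list of the grid axes (`sigmaBlur`, `sigmaNoise`,
#'   `patchSize`).
#' @slot bestCSF the simulated [CSFCurve-class] at the optimum.
#' @aliases CSFFitResult
#' @exportClass CSFFitResult
setClass("CSFFitResult",
  representation(sigmaBlur = "numeric", sigmaNoise = "numeric",
                 patchSize = "integer", l1 = "numeric",
                 landscape = "array", grid = "list", bestCSF = "CSFCurve"),
  validity = function(object) {
    if (abs(min(object@landscape, na.rm = TRUE) - object@l1) > 1e-9)
      return("l1 must equal the landscape minimum")
    TRUE
  })

#' Per-condition classification accuracy
#'
#' Accuracy of an observer (rat, readout or simulated responder) indexed by
#' stimulus condition, e.g. a size x azimuth matrix. Stored as a named
#' numeric array with dimnames giving the condition labels.
#'
#' @slot accuracy numeric array in \[0, 1\] with dimnames.
#' @slot metadata free-form provenance list (layer, run, scale, ...).
#' @aliases AccuracyMatrix
#' @exportClass AccuracyMatrix
setClass("AccuracyMatrix",
  representation(accuracy = "array", metadata = "list"),
  validity = function(object) {
    if (any(is.finite(object@accuracy) &
            (object@accuracy < 0 | object@accuracy > 1)))
      return("accuracies must lie in [0, 1]")
    TRUE
  })

#' @param accuracy,metadata see slots.
#' @rdname AccuracyMatrix-class
#' @export
accuracyMatrix <- function(accuracy, metadata = list()) {
  new("AccuracyMatrix", accuracy = as.array(accuracy), metadata = metadata)
}

#' Classification-image saliency map
#'
#' Per-pixel diagnosticity of visibility (bubbles estimator) or intensity
#' (structural-variant estimator) for a target choice, with permutation
#' significance masks. Pixels never covered by any mask are NA in `S` and
#' FALSE in `covered`.
#'
#' @slot S per-pixel saliency (matrix, may contain NA).
#' @slot sigSalient,sigAntisalient disjoint logical masks of significantly
#'   salient / anti-salient pixels.
#' @slot pThreshold per-tail significance level.
#' @slot nPermutations permutations used for the null.
#' @slot covered logical matrix of pixels with a defined saliency value.
#' @aliases SaliencyMap
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(S = "matrix", sigSalient = "matrix",
                 sigAntisalient = "matrix", pThreshold = "numeric",
                 nPermutations = "integer", covered = "matrix"),
  validity = function(object) {
    if (any(object@sigSalient & object@sigAntisalient))
      return("significance masks must be disjoint")
    if (!identical(dim(object@S), dim(object@sigSalient)) ||
        !identical(dim(object@S), dim(object@sigAntisalient)))
      return("mask dimensions must match S")
    TRUE
  })

#' Ideal-observer template store
#'
#' A classifier with perfect knowledge of every view an object can take:
#' it stores one template per (object, view) and assigns the label of the
#' template with the largest dot product against the input.
#'
#' @slot templates list of image matrices.
#' @slot labels character vector, one class label per template.
#' @aliases IdealObserver
#' @exportClass IdealObserver
setClass("IdealObserver",
  representation(templates = "list", labels = "character"),
  validity = function(object) {
    if (length(object@templates) != length(object@labels))
      return("one label per template required")
    if (length(unique(object@labels)) < 1) return("need >= 1 class")
    TRUE
  })

#' @param templates,labels see slots.
#' @rdname IdealObserver-class
#' @export
idealObserver <- function(templates, labels) {
  new("IdealObserver", templates = templates, labels = as.character(labels))
}

#' Unit subsample of a network layer
#'
#' @slot layerId probed layer (1-based weight-layer index).
#' @slot indices unique sampled unit indices.
#' @slot requested requested population size (capped at the layer size).
#' @aliases UnitSample
#' @exportClass UnitSample
setClass("UnitSample",
  representation(layerId = "integer", indices = "integer",
                 requested = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@indices)) return("indices must be unique")
    TRUE
  })

#' Parameter-matched multi-layer perceptron
#'
#' A cascade of 16 affine stages with ReLU between them (none after the
#' last), dimensioned to match a 16-weight-layer convolutional reference in
#' depth and total parameter count.
#'
#' @slot dims layer dimensionalities N0..N16.
#' @slot weights,biases per-stage weight matrices (Nl x Nl-1) and bias
#'   vectors.
#' @slot seed initialization seed.
#' @aliases MLPNetwork
#' @exportClass MLPNetwork
setClass("MLPNetwork",
  representation(dims = "numeric", weights = "list", biases = "list",
                 seed = "integer"))

#' Convolutional network (VGG-16 layout)
#'
#' The standard 16-weight-layer architecture: 13 3x3 convolutions in five
#' blocks with 2x2 max pooling, then 3 fully connected stages ending in a
#' 1000-way output. Weights are randomly initialized (fan-in uniform,
#' seeded); pretrained weights are not bundled.
#'
#' @slot layers list of per-layer descriptors (type, channels/dims,
#'   pooling).
#' @slot weights,biases per-layer parameters.
#' @slot inputSize spatial input resolution the instance was built for.
#' @slot channels input channels (grayscale inputs are replicated).
#' @slot seed initialization seed.
#' @aliases ConvNetwork
#' @exportClass ConvNetwork
setClass("ConvNetwork",
  representation(layers = "list", weights = "list", biases = "list",
                 inputSize = "integer", channels = "integer",
                 seed = "integer"))

#' Experiment report container
#'
#' Named artifacts produced by one of the experiment pipelines plus the
#' provenance (seed, config) needed to reproduce them.
#'
#' @slot experiment experiment name.
#' @slot artifacts named list of results.
#' @slot provenance named list (seed, config, package version).
#' @aliases ExperimentReport
#' @exportClass ExperimentReport
setClass("ExperimentReport",
  representation(experiment = "character", artifacts = "list",
                 provenance = "list"))
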