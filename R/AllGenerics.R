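#' @name ratvision-generics
#' @title Generics and accessors
#' @description Accessor generics for the package's S4 containers and the
#'   network generics (`parameterCount`, `extractActivations`).
NULL

#' @param object an S4 object from this package.
#' @rdname ratvision-generics
#' @export
setGeneric("nus", function(object) standardGeneric("nus"))
#' @rdname ratvision-generics
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))
#' @rdname ratvision-generics
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname ratvision-generics
#' @export
setGeneric("saliency", function(object) standardGeneric("saliency"))
#' @rdname ratvision-generics
#' @export
setGeneric("salientMask", function(object) standardGeneric("salientMask"))
#' @rdname ratvision-generics
#' @export
setGeneric("antisalientMask",
           function(object) standardGeneric("antisalientMask"))

#' Count network parameters
#'
#' Weights and biases per layer plus totals. `millions` is the raw count
#' rounded to the nearest million; `totalRoundedM` sums the per-layer
#' rounded values (the convention used when an architecture table reports
#' a rounded-million column and its total).
#'
#' @param network an [MLPNetwork-class], [ConvNetwork-class], or a layer
#'   specification list from [mlpTable1Spec()] / [vgg16LayerSpec()].
#' @return list with `table` (data.frame: layer, label, raw, millions),
#'   `totalRaw`, `totalM` (total rounded to millions), `totalRoundedM`.
#' @export
setGeneric("parameterCount", function(network) {
  standardGeneric("parameterCount")
})

#' Extract pre-nonlinearity layer activations
#'
#' Runs the network forward and records, for each stimulus, the responses
#' of every unit of the requested weight layer *before* the ReLU gate.
#'
#' @param network an [MLPNetwork-class] or [ConvNetwork-class].
#' @param layerId weight-layer index in 1..16.
#' @param images list of grayscale image matrices (or a stimulus x pixel
#'   matrix for the MLP).
#' @return numeric matrix, stimuli in rows, units in columns.
#' @export
setGeneric("extractActivations", function(network, layerId, images) {
  standardGeneric("extractActivations")
})

#' @rdname ratvision-generics
#' @export
setMethod("nus", "CSFCurve", function(object) object@nus)
#' @rdname ratvision-generics
#' @export
setMethod("sensitivity", "CSFCurve", function(object) object@sensitivity)
#' @rdname ratvision-generics
#' @export
setMethod("accuracy", "AccuracyMatrix", function(object) object@accuracy)
#' @rdname ratvision-generics
#' @export
setMethod("saliency", "SaliencyMap", function(object) object@S)
#' @rdname ratvision-generics
#' @export
setMethod("salientMask", "SaliencyMap", function(object) object@sigSalient)
#' @rdname ratvision-generics
#' @export
setMethod("antisalientMask", "SaliencyMap",
          function(object) object@sigAntisalient)

setMethod("show", "ViewingGeometry", function(object) {
  cat(sprintf(
    "ViewingGeometry: d=%g cm, screen %gx%g cm, %dx%d px, ppd=%.3f\n",
    object@d, object@screenW, object@screenH, object@resW, object@resH,
    object@ppd))
})

setMethod("show", "ObjectModel", function(object) {
  cat(sprintf("ObjectModel '%s': %d lobes, intensity %.2f\n",
              object@objectId, length(object@lobes), object@intensity))
})

setMethod("show", "CSFCurve", function(object) {
  pk <- which.max(object@sensitivity)
  cat(sprintf(
    "CSFCurve: %d frequencies in [%.3g, %.3g] cyc/deg; peak %.3g at %.3g\n",
    length(object@nus), min(object@nus), max(object@nus),
    object@sensitivity[pk], object@nus[pk]))
})

setMethod("show", "CSFFitResult", function(object) {
  cat(sprintf(
    "CSFFitResult: sigmaBlur=%g px, sigmaNoise=%g, patch=%d, L1=%.4g\n",
    object@sigmaBlur, object@sigmaNoise, object@patchSize, object@l1))
})

setMethod("show", "AccuracyMatrix", function(object) {
  cat(sprintf("AccuracyMatrix [%s]: mean accuracy %.3f\n",
              paste(dim(object@accuracy), collapse = " x "),
              mean(object@accuracy, na.rm = TRUE)))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf(
    "SaliencyMap %dx%d: %d salient, %d anti-salient px (p<%g, %d perms)\n",
    nrow(object@S), ncol(object@S), sum(object@sigSalient),
    sum(object@sigAntisalient), object@pThreshold, object@nPermutations))
})

setMethod("show", "MLPNetwork", function(object) {
  cat(sprintf("MLPNetwork: %d affine stages, dims %s -> ... -> %d\n",
              length(object@dims) - 1L, object@dims[1],
              object@dims[length(object@dims)]))
})

setMethod("show", "ConvNetwork", function(object) {
  nconv <- sum(vapply(object@layers, function(l) l$type == "conv", TRUE))
  cat(sprintf(
    "ConvNetwork: %d conv + %d fc weight layers, input %dx%d, %d channels\n",
    nconv, length(object@layers) - nconv, object@inputSize,
    object@inputSize, object@channels))
})

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport '%s' with artifacts: %s\n",
              object@experiment,
              paste(names(object@artifacts), collapse = ", ")))
})
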