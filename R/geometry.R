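#' On-screen displacement produced by a head rotation
#'
#' A head rotation spanning `thetaDeg` degrees in front of a display at
#' distance `d` sweeps the gaze point across `2 * d * tan(theta/2)` cm of
#' screen. The function is odd in `thetaDeg` and strictly increasing on
#' (-180, 180).
#'
#' @param thetaDeg rotation span in degrees, |theta| < 180.
#' @param d viewing distance in cm.
#' @return displacement in cm.
#' @examples
#' angularDisplacement(60, 30) # 34.64 cm
#' @export
angularDisplacement <- function(thetaDeg, d) {
  if (any(abs(thetaDeg) >= 180)) stop("|thetaDeg| must be < 180")
  2 * d * tan(thetaDeg * pi / 360)
}

#' Displacement as a fraction of the image size
#'
#' Converts a screen displacement span (cm) into the half-width of the
#' uniform translation distribution, expressed as a fraction of the image
#' size: `delta / (2 * screenDim)`. The cm-to-pixel factor cancels because
#' image size and displacement scale identically.
#'
#' @param deltaCm displacement span in cm (e.g. from
#'   [angularDisplacement()]).
#' @param screenDimCm physical screen extent along the same axis, cm.
#' @return half-width of the translation distribution in image-fraction
#'   units.
#' @export
displacementFraction <- function(deltaCm, screenDimCm) {
  if (any(screenDimCm <= 0)) stop("screenDimCm must be > 0")
  deltaCm / (2 * screenDimCm)
}

#' Draw one head pose and convert it to image transformations
#'
#' Pitch, roll and yaw are drawn uniformly on +/- span/2. Roll maps
#' directly to the in-plane rotation. A signed yaw (pitch) angle theta
#' deflects the gaze by `d * tan(theta)` cm horizontally (vertically),
#' which equals `angularDisplacement(2 * theta, d) / 2`; dividing by the
#' screen extent gives the translation fraction, so the extreme draws land
#' exactly on `displacementFraction(angularDisplacement(span, d), screen)`.
#'
#' @param ranges a [HeadPoseRanges-class].
#' @param geom a [ViewingGeometry-class].
#' @param seed optional integer; when NULL the current R RNG stream is
#'   used.
#' @return an [AugmentationSample-class].
#' @export
sampleHeadPose <- function(ranges, geom = viewingGeometry(), seed = NULL) {
  with_seed(seed, {
    roll <- runif(1, -ranges@rollSpan / 2, ranges@rollSpan / 2)
    pitch <- runif(1, -ranges@pitchSpan / 2, ranges@pitchSpan / 2)
    yaw <- runif(1, -ranges@yawSpan / 2, ranges@yawSpan / 2)
    xf <- displacementFraction(angularDisplacement(2 * yaw, geom@d),
                               geom@screenW)
    yf <- displacementFraction(angularDisplacement(2 * pitch, geom@d),
                               geom@screenH)
    augmentationSample(alphaDeg = roll, xFrac = xf, yFrac = yf)
  })
}

#' Apply an in-plane rotation and translation to an image
#'
#' Rotates by `alphaDeg` about the geometric image center, then translates
#' by `(xFrac * width, yFrac * height)` pixels. Bilinear interpolation;
#' regions mapped from outside the frame are filled with background 0.
#'
#' @param image square numeric matrix in \[0, 1\].
#' @param sample an [AugmentationSample-class].
#' @return transformed image, same dimensions.
#' @export
applyAffine <- function(image, sample) {
  assert_image(image)
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr != nc) stop("applyAffine expects a square image")
  a <- sample@alphaDeg * pi / 180
  cx <- (nc - 1) / 2
  cy <- (nr - 1) / 2
  tx <- sample@xFrac * nc
  ty <- sample@yFrac * nr
  # inverse map: src = R(-alpha) %*% (dst - c - t) + c
  ca <- cos(a)
  sa <- sin(a)
  m <- c(ca, -sa, sa, ca,
         cx - ca * (cx + tx) - sa * (cy + ty),
         cy + sa * (cx + tx) - ca * (cy + ty))
  cpp_affine_warp(image, m, TRUE, 0)
}

#' Apply the blur + noise front end
#'
#' Gaussian blur with SD `sigmaBlur` pixels (separable convolution, reflect
#' padding), then i.i.d. additive Gaussian noise with SD `sigmaNoise`,
#' then clipping to \[0, 1\]. Blur precedes noise: blur stands in for the
#' eye's optics, noise for downstream neural variability.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param params a [NoiseBlurParams-class].
#' @param seed optional integer seed for the noise draw.
#' @return degraded image.
#' @export
applyBlurNoise <- function(image, params, seed = NULL) {
  assert_image(image)
  out <- cpp_sep_blur(image, params@sigmaBlur)
  sub <- if (is.null(seed)) next_subseed() else as.integer(seed)
  cpp_add_noise(out, params@sigmaNoise, sub, TRUE)
}

#' Run the full augmentation pipeline on one image
#'
#' One fresh head-pose draw (affine jitter) followed by blur and noise.
#' Occlusion masks, when used, are applied upstream of this call.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param config an [AugmentationConfig-class].
#' @param seed optional integer seed covering both the pose and noise
#'   draws.
#' @return augmented image.
#' @export
augment <- function(image, config, seed = NULL) {
  with_seed(seed, {
    pose <- sampleHeadPose(config@ranges, config@geom)
    out <- applyAffine(image, pose)
    applyBlurNoise(out, config@noiseBlur)
  })
}
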