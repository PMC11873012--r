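#' Grating stimulus specification
#'
#' @slot nu spatial frequency (cycles/deg).
#' @slot contrast Michelson contrast in \[0, 1\].
#' @slot orientation orientation angle (radians).
#' @slot phase phase angle (radians).
#' @aliases GratingSpec
#' @exportClass GratingSpec
setClass("GratingSpec",
  representation(nu = "numeric", contrast = "numeric",
                 orientation = "numeric", phase = "numeric"),
  validity = function(object) {
    if (object@nu <= 0) return("nu must be > 0")
    if (object@contrast < 0 || object@contrast > 1)
      return("contrast must lie in [0, 1]")
    TRUE
  })

#' @param nu,contrast,orientation,phase see slots.
#' @rdname GratingSpec-class
#' @export
gratingSpec <- function(nu, contrast, orientation = 0, phase = 0) {
  new("GratingSpec", nu = nu, contrast = contrast,
      orientation = orientation, phase = phase)
}

#' Default contrast and spatial-frequency grids
#'
#' The contrast grid is 12 log-spaced values in \[0.005, 1\]. The spatial
#' frequency grid is 8 log-spaced values (0.2 dex apart) containing 0.04,
#' 0.1 and 1.0 cycles/deg exactly — the frequencies at which the rat CSF's
#' zeros and peak are reported.
#'
#' @return numeric vector.
#' @export
defaultContrastGrid <- function() {
  10^seq(log10(0.005), 0, length.out = 12)
}

#' @rdname defaultContrastGrid
#' @export
defaultNuGrid <- function() {
  c(0.04, 0.063, 0.1, 0.158, 0.251, 0.398, 0.631, 1.0)
}

#' Render a sine-wave grating
#'
#' Pixel value `0.5 + (c/2) sin(2 pi nu u + phase)` where `u` is the
#' position in degrees along the orientation axis (pixels divided by ppd).
#' Mean luminance 0.5.
#'
#' @param spec a [GratingSpec-class].
#' @param geom a [ViewingGeometry-class].
#' @return image matrix; errors if `nu` exceeds the Nyquist frequency
#'   `ppd / 2`.
#' @export
makeGrating <- function(spec, geom = viewingGeometry()) {
  if (spec@nu > geom@ppd / 2)
    stop(sprintf("nu = %g cyc/deg exceeds Nyquist (%g) for ppd %g",
                 spec@nu, geom@ppd / 2, geom@ppd))
  cpp_grating(geom@resH, geom@resW, spec@nu, spec@contrast,
              spec@orientation, spec@phase, geom@ppd)
}

patch_grid <- function(nr, nc, p) {
  p <- as.integer(p)
  if (p > min(nr, nc)) stop("patch_size larger than the image side")
  gr <- nr %/% p
  gc <- nc %/% p
  list(p = p, off_r = (nr - gr * p) %/% 2L, off_c = (nc - gc * p) %/% 2L,
       grid_r = gr, grid_c = gc)
}

#' Patch-contrast features of an image
#'
#' Contrast measured as the (population) standard deviation of pixel
#' intensities within each cell of a regular non-overlapping grid of
#' `patchSize` x `patchSize` patches, anchored at the top-left of the
#' largest centered multiple of the patch size.
#'
#' @param image numeric matrix.
#' @param patchSize patch side in pixels.
#' @return numeric feature vector, one SD per patch.
#' @export
patchContrasts <- function(image, patchSize) {
  assert_image(image)
  g <- patch_grid(nrow(image), ncol(image), patchSize)
  as.numeric(cpp_patch_sd(image, g$p, g$off_r, g$off_c, g$grid_r,
                          g$grid_c))
}

#' Train the grating-detection observer
#'
#' Simulates the grating-detection task: a linear SVM is trained on
#' patch-contrast features to discriminate blurred + noisy sine gratings
#' (random phase and orientation, contrast drawn uniformly over the test
#' grid so one detector serves the full psychometric) from noisy uniform
#' mid-gray images.
#'
#' @param nu spatial frequency (cycles/deg).
#' @param blurNoise a [NoiseBlurParams-class].
#' @param patchSize patch side in px.
#' @param nPerClass training samples per class.
#' @param contrastGrid contrast levels pooled during training.
#' @param geom a [ViewingGeometry-class].
#' @param falseAlarmRate target probability of reporting "grating" on a
#'   signal-free (gray) trial: the SVM's decision threshold is calibrated
#'   on a fresh set of gray trials so the observer answers "grating" only
#'   with positive evidence (default 0.05). This pins the psychometric
#'   baseline at a low, false-alarm-matched level, as in a yes/no
#'   detection task with a conservative criterion.
#' @param seed optional integer seed.
#' @return a `DetectionObserver` (list with the fitted SVM, decision
#'   criterion and settings).
#' @export
trainDetectionObserver <- function(nu, blurNoise, patchSize = 28L,
                                   nPerClass = 5000L,
                                   contrastGrid = defaultContrastGrid(),
                                   geom = viewingGeometry(),
                                   falseAlarmRate = 0.05, seed = NULL) {
  with_seed(seed, {
    g <- patch_grid(geom@resH, geom@resW, patchSize)
    contrasts <- sample(contrastGrid, nPerClass, replace = TRUE)
    fg <- cpp_grating_features(nPerClass, geom@resH, geom@resW, nu,
                               contrasts, geom@ppd, blurNoise@sigmaBlur,
                               blurNoise@sigmaNoise, g$p, g$off_r, g$off_c,
                               g$grid_r, g$grid_c, next_subseed())
    fb <- cpp_gray_features(nPerClass, geom@resH, geom@resW,
                            blurNoise@sigmaNoise, g$p, g$off_r, g$off_c,
                            g$grid_r, g$grid_c, next_subseed())
    X <- rbind(fg, fb)
    if (all(abs(X - X[1]) < 1e-12))
      stop("degenerate features: all patch contrasts identical")
    y <- factor(rep(c("grating", "gray"), each = nPerClass),
                levels = c("grating", "gray"))
    fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = TRUE)
    # orient decision values so grating evidence is positive
    dv_tr <- attr(predict(fit, fg, decision.values = TRUE),
                  "decision.values")
    orient <- if (mean(dv_tr) >= 0) 1 else -1
    # criterion: (1 - FA) quantile of evidence on fresh gray trials
    fb2 <- cpp_gray_features(max(nPerClass, 200L), geom@resH, geom@resW,
                             blurNoise@sigmaNoise, g$p, g$off_r, g$off_c,
                             g$grid_r, g$grid_c, next_subseed())
    dv_gray <- orient * attr(predict(fit, fb2, decision.values = TRUE),
                             "decision.values")
    crit <- stats::quantile(as.numeric(dv_gray), 1 - falseAlarmRate,
                            names = FALSE)
    structure(list(svm = fit, orient = orient, criterion = crit,
                   falseAlarmRate = falseAlarmRate, nu = nu,
                   blurNoise = blurNoise, patch = g, geom = geom),
              class = "DetectionObserver")
  })
}

detector_says_grating <- function(detector, feats) {
  dv <- attr(predict(detector$svm, feats, decision.values = TRUE),
             "decision.values")
  detector$orient * as.numeric(dv) > detector$criterion
}

psycho_predict <- function(detector, nu, contrasts, nTrials, nReps, seed) {
  g <- detector$patch
  geom <- detector$geom
  bn <- detector$blurNoise
  with_seed(seed, {
    p_mat <- vapply(seq_len(nReps), function(rep) {
      feats <- cpp_psycho_features(nTrials, geom@resH, geom@resW, nu,
                                   contrasts, geom@ppd, bn@sigmaBlur,
                                   bn@sigmaNoise, g$p, g$off_r, g$off_c,
                                   g$grid_r, g$grid_c, next_subseed())
      hit <- matrix(detector_says_grating(detector, feats),
                    nrow = length(contrasts))
      rowMeans(hit)
    }, numeric(length(contrasts)))
    p_mat
  })
}

#' Detection probability at one contrast
#'
#' Fraction of fresh grating trials the detector classifies as "grating",
#' repeated `nReps` times.
#'
#' @param detector a `DetectionObserver` from [trainDetectionObserver()].
#' @param nu spatial frequency; should match the detector's.
#' @param contrast grating contrast.
#' @param nTrials fresh trials per repetition.
#' @param nReps repetitions (the SD is taken over these).
#' @param seed optional integer seed.
#' @return list with `p` (mean) and `sd`.
#' @export
detectionProbability <- function(detector, nu, contrast, nTrials = 100L,
                                 nReps = 3L, seed = NULL) {
  p_mat <- psycho_predict(detector, nu, contrast, nTrials, nReps, seed)
  list(p = mean(p_mat), sd = stats::sd(as.numeric(p_mat)))
}

#' Measure a full psychometric curve
#'
#' @param detector a `DetectionObserver`.
#' @param contrasts ascending contrast grid.
#' @param nTrials,nReps trials per contrast per repetition, repetitions.
#' @param seed optional integer seed.
#' @return a [PsychometricCurve-class].
#' @export
measurePsychometric <- function(detector, contrasts = defaultContrastGrid(),
                                nTrials = 100L, nReps = 3L, seed = NULL) {
  p_mat <- psycho_predict(detector, detector$nu, contrasts, nTrials, nReps,
                          seed)
  psychometricCurve(contrasts, rowMeans(p_mat), apply(p_mat, 1, stats::sd))
}

#' Contrast threshold of a psychometric curve
#'
#' The threshold xi is the contrast of the first upward crossing of
#' p = 0.5, located by linear interpolation in log-contrast. If the curve
#' starts at or above 0.5, the lowest tested contrast is returned; if it
#' never reaches 0.5, the threshold is +Inf (sensitivity 0).
#'
#' @param curve a [PsychometricCurve-class].
#' @return threshold contrast (possibly `Inf`).
#' @export
contrastThreshold <- function(curve) {
  p <- curve@pDetect
  cc <- curve@contrasts
  if (length(p) == 0) stop("empty psychometric curve")
  if (p[1] >= 0.5) return(cc[1])
  idx <- which(p >= 0.5)
  if (length(idx) == 0) return(Inf)
  i <- idx[1]
  lx <- log(cc[i - 1]) +
    (0.5 - p[i - 1]) / (p[i] - p[i - 1]) * (log(cc[i]) - log(cc[i - 1]))
  exp(lx)
}

#' Compute the simulated observer's CSF
#'
#' For every spatial frequency: train the detection observer at the given
#' blur/noise/patch settings, measure its psychometric curve and take the
#' reciprocal of the contrast threshold as the sensitivity (an infinite
#' threshold maps to sensitivity 0).
#'
#' @param blurNoise a [NoiseBlurParams-class].
#' @param patchSize patch side in px.
#' @param nuGrid spatial frequency grid (cycles/deg).
#' @param contrastGrid ascending contrast grid.
#' @param geom a [ViewingGeometry-class].
#' @param nPerClass training samples per class.
#' @param nTrials,nReps psychometric trials per contrast and repetitions.
#' @param seed optional integer seed.
#' @return a [CSFCurve-class].
#' @export
computeCSF <- function(blurNoise, patchSize = 28L,
                       nuGrid = defaultNuGrid(),
                       contrastGrid = defaultContrastGrid(),
                       geom = viewingGeometry(), nPerClass = 500L,
                       nTrials = 15L, nReps = 3L, seed = NULL) {
  if (length(nuGrid) == 0 || length(contrastGrid) == 0)
    stop("nuGrid and contrastGrid must be non-empty")
  with_seed(seed, {
    sens <- vapply(nuGrid, function(nu) {
      det <- trainDetectionObserver(nu, blurNoise, patchSize, nPerClass,
                                    contrastGrid, geom)
      pc <- measurePsychometric(det, contrastGrid, nTrials, nReps)
      xi <- contrastThreshold(pc)
      if (is.finite(xi)) 1 / xi else 0
    }, numeric(1))
    csfCurve(nuGrid, sens)
  })
}

#' Grid-search blur and noise against a target CSF
#'
#' Simulates the observer's CSF over a grid of (sigmaBlur, sigmaNoise,
#' patchSize) combinations and returns the cell minimizing the L1 distance
#' `sum_nu |sigma_sim(nu) - sigma_target(nu)|`, together with the full L1
#' landscape.
#'
#' @param target target [CSFCurve-class]; the simulated curves share its
#'   frequency grid.
#' @param sigmaBlurGrid,sigmaNoiseGrid,patchSizes grid axes.
#' @param contrastGrid ascending contrast grid.
#' @param geom a [ViewingGeometry-class].
#' @param nPerClass,nTrials,nReps simulation sizes per cell (see
#'   [computeCSF()]).
#' @param seed optional integer seed.
#' @param verbose print per-cell progress.
#' @return a [CSFFitResult-class].
#' @export
fitCSF <- function(target, sigmaBlurGrid, sigmaNoiseGrid,
                   patchSizes = 28L, contrastGrid = defaultContrastGrid(),
                   geom = viewingGeometry(), nPerClass = 500L,
                   nTrials = 15L, nReps = 3L, seed = NULL,
                   verbose = FALSE) {
  patchSizes <- as.integer(patchSizes)
  land <- array(NA_real_,
                dim = c(length(sigmaBlurGrid), length(sigmaNoiseGrid),
                        length(patchSizes)),
                dimnames = list(sigmaBlurGrid, sigmaNoiseGrid, patchSizes))
  best <- NULL
  with_seed(seed, {
    for (k in seq_along(patchSizes)) {
      for (i in seq_along(sigmaBlurGrid)) {
        for (j in seq_along(sigmaNoiseGrid)) {
          sim <- computeCSF(
            noiseBlurParams(sigmaBlurGrid[i], sigmaNoiseGrid[j]),
            patchSizes[k], target@nus, contrastGrid, geom, nPerClass,
            nTrials, nReps)
          l1 <- sum(abs(sim@sensitivity - target@sensitivity))
          land[i, j, k] <- l1
          if (verbose)
            message(sprintf("blur=%g noise=%g patch=%d: L1=%.3f",
                            sigmaBlurGrid[i], sigmaNoiseGrid[j],
                            patchSizes[k], l1))
          if (is.null(best) || l1 < best$l1)
            best <- list(i = i, j = j, k = k, l1 = l1, csf = sim)
        }
      }
    }
  })
  new("CSFFitResult", sigmaBlur = sigmaBlurGrid[best$i],
      sigmaNoise = sigmaNoiseGrid[best$j], patchSize = patchSizes[best$k],
      l1 = best$l1, landscape = land,
      grid = list(sigmaBlur = sigmaBlurGrid, sigmaNoise = sigmaNoiseGrid,
                  patchSize = patchSizes),
      bestCSF = best$csf)
}

#' Peak frequency of a measured CSF
#'
#' The spatial frequency at which a CSF attains its maximum, read from a
#' fitted truncated log-parabola (the standard parametric CSF descriptor,
#' here with independent left/right half-widths to allow the asymmetric
#' band-pass shape). Fitting a smooth descriptor decouples the peak
#' estimate from the sampling grid: the raw `which.max` of a measured
#' curve is quantized to the tested frequencies and, for a flat-topped
#' curve, dominated by sampling noise.
#'
#' @param curve a [CSFCurve-class].
#' @return peak spatial frequency in cycles/deg (continuous scale).
#' @export
csfPeakFrequency <- function(curve) {
  nus <- curve@nus
  sens <- curve@sensitivity
  if (length(nus) < 4) return(nus[which.max(sens)])
  obj <- function(par) {
    lp <- par[1]
    A <- par[2]
    wl <- abs(par[3])
    wr <- abs(par[4])
    pred <- vapply(log10(nus), function(lx) {
      half <- if (lx <= lp) -wl else wr
      max(A * (1 - ((lx - lp) / half)^2), 0)
    }, numeric(1))
    sum((pred - sens)^2)
  }
  start <- c(log10(nus[which.max(sens)]), max(sens), 0.4, 1.0)
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-10))
  peak <- 10^o$par[1]
  # keep the estimate inside the measured band
  min(max(peak, min(nus)), max(nus))
}

#' Parametric stand-in for the rat contrast sensitivity function
#'
#' A smooth unimodal curve on the log-frequency axis built from the
#' published descriptors of the Long-Evans rat CSF: maximum at 0.1
#' cycles/deg and zero sensitivity at 0.04 and 1.0 cycles/deg. Two
#' half-parabolas in log-frequency (one per side of the peak, each
#' vanishing at its zero crossing and clipped below at 0) give an
#' asymmetric band-pass shape; the numeric values of the measured curve
#' are not published, so the peak sensitivity is a free parameter.
#'
#' @param peakSensitivity sensitivity at the peak (default 20).
#' @param nuGrid frequency grid to evaluate on.
#' @param peakNu,zeroLow,zeroHigh shape anchors (cycles/deg).
#' @return a [CSFCurve-class].
#' @export
ratCSFStandin <- function(peakSensitivity = 20, nuGrid = defaultNuGrid(),
                          peakNu = 0.1, zeroLow = 0.04, zeroHigh = 1.0) {
  lp <- log10(peakNu)
  sens <- vapply(nuGrid, function(nu) {
    lx <- log10(nu)
    half <- if (lx <= lp) log10(zeroLow) - lp else log10(zeroHigh) - lp
    v <- peakSensitivity * (1 - ((lx - lp) / half)^2)
    max(v, 0)
  }, numeric(1))
  csfCurve(nuGrid, sens)
}
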