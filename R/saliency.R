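#' Bubble-mask specification
#'
#' Occlusion masks are built by sprinkling `nBubbles` Gaussian apertures
#' (transparency bubbles) with centers uniform in a centered square
#' spanning `regionFraction` of the image, the aperture sum clipped at 1.
#' The bubble size is stated as a visual angle; it is converted to the
#' Gaussian SD by interpreting it as the full width at half maximum
#' (FWHM = 2.355 sigma).
#'
#' @param nBubbles number of apertures per mask (default 40).
#' @param bubbleDeg aperture size in degrees of visual angle (default 2).
#' @param regionFraction side of the centered sprinkling region as a
#'   fraction of the image side (default 0.7).
#' @param geom a [ViewingGeometry-class] giving the ppd factor.
#' @return list with fields `nBubbles`, `sigmaPx`, `regionFraction`.
#' @export
bubbleMaskSpec <- function(nBubbles = 40L, bubbleDeg = 2,
                           regionFraction = 0.7,
                           geom = viewingGeometry()) {
  if (nBubbles < 0) stop("nBubbles must be >= 0")
  if (regionFraction <= 0 || regionFraction > 1)
    stop("regionFraction must lie in (0, 1]")
  fwhm_px <- bubbleDeg * geom@ppd
  list(nBubbles = as.integer(nBubbles),
       sigmaPx = fwhm_px / (2 * sqrt(2 * log(2))),
       regionFraction = regionFraction)
}

#' Generate bubble occlusion masks
#'
#' @param n number of masks.
#' @param spec a [bubbleMaskSpec()] list.
#' @param imageSize side of the square frame in pixels.
#' @param seed optional integer seed.
#' @return n x imageSize^2 matrix of mask transparencies in \[0, 1\]
#'   (pixels in column-major order); use [maskAsMatrix()] to reshape one
#'   row.
#' @export
makeBubbleMasks <- function(n, spec, imageSize, seed = NULL) {
  sub <- if (is.null(seed)) next_subseed() else as.integer(seed)
  cpp_bubble_masks(as.integer(n), spec$nBubbles, spec$sigmaPx,
                   as.integer(imageSize), spec$regionFraction, sub)
}

#' @param masks a mask matrix from [makeBubbleMasks()].
#' @param i row index.
#' @rdname makeBubbleMasks
#' @export
maskAsMatrix <- function(masks, i = 1L) {
  side <- as.integer(sqrt(ncol(masks)))
  matrix(masks[i, ], nrow = side)
}

#' Occlude an image with a transparency mask
#'
#' Per-pixel convex combination with a uniform black background:
#' `p* = bkg * (1 - m) + p * m` with `bkg = 0`, i.e. `p * m`.
#'
#' @param image image matrix.
#' @param mask transparency matrix of the same shape (1 = fully visible).
#' @return occluded image.
#' @export
applyMask <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  image * mask
}

#' Bubbles classification image (raw saliency map)
#'
#' Weighted average of the masks by response correctness:
#' `S_ij = sum_mu m_ij^mu l_mu / sum_mu |m_ij^mu|`. Pixels never covered
#' by any mask have no defined value and are returned as NA.
#'
#' @param masks n x P mask matrix (rows = trials).
#' @param labels 0/1 correctness labels, one per trial.
#' @return list with `S` (image matrix, NA where uncovered) and `covered`
#'   (logical matrix).
#' @export
bubblesSaliency <- function(masks, labels) {
  if (nrow(masks) == 0) stop("empty trial set")
  if (nrow(masks) != length(labels))
    stop("one label per mask required")
  denom <- colSums(masks)
  num <- as.numeric(crossprod(masks, labels))
  S <- ifelse(denom > 0, num / denom, NA_real_)
  side <- as.integer(sqrt(length(S)))
  list(S = matrix(S, nrow = side),
       covered = matrix(denom > 0, nrow = side))
}

# Null saliency maps under label permutation, P x nPerm.
bubbles_null_maps <- function(masks, labels, nPerm, seed = NULL) {
  perms <- with_seed(seed, {
    vapply(seq_len(nPerm), function(i) sample(labels), numeric(length(labels)))
  })
  denom <- colSums(masks)
  nulls <- crossprod(masks, perms)
  nulls / ifelse(denom > 0, denom, NA_real_)
}

#' Permutation significance test for the bubbles estimator
#'
#' Builds the null distribution of each pixel's saliency from random
#' permutations of the correctness vector. A covered pixel is
#' significantly salient if its observed saliency exceeds the
#' interpolated (1 - pTh) quantile of its null, and anti-salient if it
#' falls below the pTh quantile (one-tailed tests, no multiplicity
#' correction).
#'
#' @param masks n x P mask matrix.
#' @param labels 0/1 correctness labels.
#' @param nPerm number of permutations (default 1000).
#' @param pTh per-tail significance level (default 0.05).
#' @param seed optional integer seed.
#' @param returnNull also return the P x nPerm null matrix (used by
#'   [areaMatchedThreshold()]).
#' @return a [SaliencyMap-class] (or a list with `map` and `null`).
#' @export
permutationSignificanceBubbles <- function(masks, labels, nPerm = 1000L,
                                           pTh = 0.05, seed = NULL,
                                           returnNull = FALSE) {
  if (length(unique(labels)) < 2)
    stop("permutation test needs both label values present")
  obs <- bubblesSaliency(masks, labels)
  nulls <- bubbles_null_maps(masks, labels, nPerm, seed)
  map <- significance_from_null(obs, nulls, pTh, nPerm)
  if (returnNull) list(map = map, null = nulls) else map
}

significance_from_null <- function(obs, nulls, pTh, nPerm) {
  hi <- cpp_row_quantile(nulls, 1 - pTh)
  lo <- cpp_row_quantile(nulls, pTh)
  side <- nrow(obs$S)
  sv <- as.numeric(obs$S)
  cov <- as.numeric(obs$covered)
  sig_hi <- matrix(cov & !is.na(sv) & sv > hi, nrow = side)
  sig_lo <- matrix(cov & !is.na(sv) & sv < lo & !(sv > hi), nrow = side)
  new("SaliencyMap", S = obs$S, sigSalient = sig_hi,
      sigAntisalient = sig_lo, pThreshold = pTh,
      nPermutations = as.integer(nPerm), covered = obs$covered)
}

#' Area-matched significance threshold
#'
#' Adjusts the per-tail significance level by bisection so that the
#' salient region's area matches a target pixel count (used to compare
#' overlap metrics across observers whose salient regions would otherwise
#' differ in size).
#'
#' @param obs list with `S` and `covered` from [bubblesSaliency()] (or
#'   [tripodSaliency()]).
#' @param nulls P x nPerm null matrix.
#' @param targetArea target salient area in pixels.
#' @param tol acceptable absolute deviation in pixels (default 1).
#' @param maxIter bisection iterations.
#' @param null `"empirical"` thresholds each pixel at the interpolated
#'   null quantile (areas are limited by the permutation maximum);
#'   `"gaussian"` fits a per-pixel Gaussian to the null — its unbounded
#'   p-scale can isolate arbitrarily small regions, which is what the
#'   overlap analyses need when the matched area is small.
#' @return a [SaliencyMap-class] whose salient region has the target area
#'   (within `tol`); errors reporting the achievable range when the
#'   target cannot be reached.
#' @export
areaMatchedThreshold <- function(obs, nulls, targetArea, tol = 1,
                                 maxIter = 60L,
                                 null = c("empirical", "gaussian")) {
  null <- match.arg(null)
  if (targetArea > length(obs$S)) stop("targetArea exceeds the image area")
  if (null == "gaussian") {
    mu <- rowMeans(nulls)
    sdv <- sqrt(pmax(rowMeans(nulls^2) - mu^2, 0))
    sv <- as.numeric(obs$S)
    ok <- as.numeric(obs$covered) & !is.na(sv) & sdv > 0
    z <- rep(-Inf, length(sv))
    z[ok] <- (sv[ok] - mu[ok]) / sdv[ok]
    if (targetArea > sum(ok))
      stop(sprintf("target area %d unreachable; achievable range [0, %d]",
                   as.integer(targetArea), sum(ok)))
    side <- nrow(obs$S)
    if (targetArea == 0) {
      sig <- matrix(FALSE, side, side)
      pth <- 0
    } else {
      zk <- sort(z, decreasing = TRUE)[targetArea]
      sig <- matrix(z >= zk, side)
      pth <- stats::pnorm(zk, lower.tail = FALSE)
    }
    return(new("SaliencyMap", S = obs$S, sigSalient = sig,
               sigAntisalient = matrix(FALSE, side, side),
               pThreshold = pth, nPermutations = ncol(nulls),
               covered = obs$covered))
  }
  area_at <- function(p) {
    hi <- cpp_row_quantile(nulls, 1 - p)
    sum(obs$covered & !is.na(obs$S) & as.numeric(obs$S) > hi)
  }
  if (targetArea == 0) {
    map <- significance_from_null(obs, nulls, .Machine$double.eps,
                                  ncol(nulls))
    map@sigSalient[] <- FALSE
    return(map)
  }
  lo <- 1e-9
  hi <- 0.999999
  a_lo <- area_at(lo)
  a_hi <- area_at(hi)
  if (targetArea < a_lo || targetArea > a_hi)
    stop(sprintf("target area %d unreachable; achievable range [%d, %d]",
                 as.integer(targetArea), a_lo, a_hi))
  for (it in seq_len(maxIter)) {
    mid <- sqrt(lo * hi)
    a <- area_at(mid)
    if (abs(a - targetArea) <= tol) {
      return(significance_from_null(obs, nulls, mid, ncol(nulls)))
    }
    if (a < targetArea) lo <- mid else hi <- mid
  }
  significance_from_null(obs, nulls, sqrt(lo * hi), ncol(nulls))
}

#' Classify an image with the ideal observer
#'
#' Dot product of the input against every stored template; the label of
#' the best-matching template wins, ties broken toward the lowest template
#' index.
#'
#' @param image image matrix.
#' @param observer an [IdealObserver-class].
#' @return class label (character).
#' @export
idealObserverClassify <- function(image, observer) {
  if (length(observer@templates) == 0) stop("empty template store")
  if (!identical(dim(image), dim(observer@templates[[1]])))
    stop("image and template shapes differ")
  dots <- vapply(observer@templates, function(tp) sum(tp * image), 0)
  observer@labels[which.max(dots)]
}

#' Build the ideal observer for a set of object views
#'
#' Renders every (model, view) combination and stores the images as
#' templates labelled by object.
#'
#' @param models list of [ObjectModel-class] objects.
#' @param views list of [ViewParams-class] objects.
#' @param geom a [ViewingGeometry-class].
#' @return an [IdealObserver-class] with `length(models) * length(views)`
#'   templates.
#' @export
buildIdealObserver <- function(models, views, geom = viewingGeometry()) {
  templates <- list()
  labels <- character(0)
  for (m in models) {
    for (v in views) {
      templates[[length(templates) + 1L]] <- renderView(m, v, geom)
      labels <- c(labels, m@objectId)
    }
  }
  idealObserver(templates, labels)
}

#' Structural-variant classification image
#'
#' Difference of conditional means of the variant images:
#' `S = E[T | r = 1] - E[T | r = 0]`.
#'
#' @param trials n x P matrix of flattened variant images (or list of
#'   image matrices).
#' @param choices 0/1 choice vector (1 = classified as the target).
#' @return list with `S` (image matrix) and `covered` (all TRUE; kept for
#'   symmetry with [bubblesSaliency()]).
#' @export
tripodSaliency <- function(trials, choices) {
  if (is.list(trials)) trials <- do.call(rbind, lapply(trials, as.numeric))
  n1 <- sum(choices == 1)
  n0 <- sum(choices == 0)
  if (n1 == 0 || n0 == 0)
    stop("saliency undefined: one choice class is empty")
  S <- colMeans(trials[choices == 1, , drop = FALSE]) -
    colMeans(trials[choices == 0, , drop = FALSE])
  side <- as.integer(sqrt(length(S)))
  list(S = matrix(S, nrow = side),
       covered = matrix(TRUE, side, side))
}

#' Permutation significance test for the structural-variant estimator
#'
#' Permutes the choice vector to build each pixel's null saliency
#' distribution, fits a one-dimensional Gaussian (mean, SD) to smooth it,
#' and flags pixels in the upper (salient) or lower (anti-salient) tail
#' at level `pTh` (one-tailed tests). Pixels with zero null variance are
#' marked non-significant and counted in a message.
#'
#' @param trials n x P matrix of flattened variant images (or list).
#' @param choices 0/1 choice vector.
#' @param nPerm number of permutations (default 100).
#' @param pTh per-tail significance level (default 0.01).
#' @param seed optional integer seed.
#' @return a [SaliencyMap-class].
#' @export
permutationSignificanceTripod <- function(trials, choices, nPerm = 100L,
                                          pTh = 0.01, seed = NULL) {
  if (is.list(trials)) trials <- do.call(rbind, lapply(trials, as.numeric))
  obs <- tripodSaliency(trials, choices)
  n1 <- sum(choices == 1)
  n0 <- sum(choices == 0)
  perms <- with_seed(seed, {
    vapply(seq_len(nPerm), function(i) sample(choices),
           numeric(length(choices)))
  })
  # S_perm = T'r/n1 - T'(1-r)/n0 = T'r (1/n1 + 1/n0) - colSums(T)/n0
  tr <- crossprod(trials, perms)
  nulls <- tr * (1 / n1 + 1 / n0) -
    matrix(colSums(trials) / n0, nrow = ncol(trials), ncol = nPerm)
  mu <- rowMeans(nulls)
  sdev <- sqrt(pmax(rowMeans(nulls^2) - mu^2, 0))
  sv <- as.numeric(obs$S)
  degen <- sdev == 0
  if (any(degen))
    message(sprintf("tripod permutation test: %d pixel(s) with zero null %s",
                    sum(degen), "variance marked non-significant"))
  z_ok <- !degen
  p_hi <- rep(1, length(sv))
  p_lo <- rep(1, length(sv))
  p_hi[z_ok] <- pnorm(sv[z_ok], mu[z_ok], sdev[z_ok], lower.tail = FALSE)
  p_lo[z_ok] <- pnorm(sv[z_ok], mu[z_ok], sdev[z_ok], lower.tail = TRUE)
  side <- nrow(obs$S)
  sig_hi <- matrix(p_hi < pTh, nrow = side)
  sig_lo <- matrix(p_lo < pTh & !(p_hi < pTh), nrow = side)
  new("SaliencyMap", S = obs$S, sigSalient = sig_hi,
      sigAntisalient = sig_lo, pThreshold = pTh,
      nPermutations = as.integer(nPerm), covered = obs$covered)
}
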