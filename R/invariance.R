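#' Raw overlap of two salient regions
#'
#' Intersection over union of two boolean masks in image (screen)
#' coordinates. Defined as 0 when both masks are empty.
#'
#' @param sigA,sigB logical matrices of the same shape.
#' @return overlap fraction in \[0, 1\].
#' @export
rawOverlap <- function(sigA, sigB) {
  if (!identical(dim(sigA), dim(sigB))) stop("mask shapes differ")
  uni <- sum(sigA | sigB)
  if (uni == 0) return(0)
  sum(sigA & sigB) / uni
}

#' Realign a map from a transformed view back to the default view
#'
#' Applies the inverse of the view transformation so that maps obtained
#' for different views can be compared in object-centered (default-view)
#' coordinates: inverse horizontal shift, inverse in-plane rotation about
#' the image center, inverse size scaling about the center, and an
#' approximate azimuth inversion by horizontal re-expansion by
#' 1/cos(azimuth) about the object's vertical axis (exact inversion of an
#' orthographic 3D rotation is not a 2D affine; set
#' `azimuthCorrection = FALSE` to disable it). Logical masks are resampled
#' nearest-neighbor, numeric maps bilinearly.
#'
#' @param map numeric or logical image matrix.
#' @param view the [ViewParams-class] that produced the map's view.
#' @param geom a [ViewingGeometry-class].
#' @param defaultSizeDeg size of the default view in degrees (default 35).
#' @param azimuthCorrection apply the 1/cos horizontal re-expansion.
#' @return realigned map, same type and shape.
#' @export
alignMap <- function(map, view, geom = viewingGeometry(),
                     defaultSizeDeg = 35, azimuthCorrection = TRUE) {
  if (abs(view@azimuthDeg) >= 90)
    stop("azimuth inversion undefined for |azimuth| >= 90 degrees")
  logical_in <- is.logical(map)
  img <- if (logical_in) (map * 1) else map
  nr <- nrow(img)
  nc <- ncol(img)
  cx <- (nc - 1) / 2
  cy <- (nr - 1) / 2
  a <- view@inplaneDeg * pi / 180
  s <- view@sizeDeg / defaultSizeDeg
  caz <- if (azimuthCorrection) cos(view@azimuthDeg * pi / 180) else 1
  tx <- view@hshiftDeg * geom@ppd
  # Forward view transform of centered coords q (default view -> view):
  #   p = R(a) %*% diag(s*caz, s) %*% q + (tx, 0)
  # The aligned map samples the view map at p, so the warp's source map is
  # exactly this forward transform (y flipped into row coordinates).
  ca <- cos(a)
  sa <- sin(a)
  # In row/col coords, y points down; an in-plane rotation by +a (counter-
  # clockwise on screen) is a rotation by -a in (col, row) coordinates.
  a11 <- ca * s * caz
  a12 <- sa * s
  a21 <- -sa * s * caz
  a22 <- ca * s
  m <- c(a11, a21, a12, a22,
         cx + tx - a11 * cx - a12 * cy,
         cy - a21 * cx - a22 * cy)
  out <- cpp_affine_warp(img, m, !logical_in, 0)
  if (logical_in) matrix(out > 0.5, nrow = nr) else out
}

#' Aligned overlap of two salient regions
#'
#' Realigns both masks to default-view coordinates with [alignMap()] and
#' takes their intersection over union: high values diagnose an
#' object-centered strategy even when the raw (screen-coordinate) overlap
#' is low.
#'
#' @param mapA,mapB logical masks.
#' @param viewA,viewB the views that produced them.
#' @param geom a [ViewingGeometry-class].
#' @param ... passed to [alignMap()].
#' @return overlap fraction in \[0, 1\].
#' @export
alignedOverlap <- function(mapA, viewA, mapB, viewB,
                           geom = viewingGeometry(), ...) {
  rawOverlap(alignMap(mapA, viewA, geom, ...),
             alignMap(mapB, viewB, geom, ...))
}

#' Pearson correlation between two saliency maps
#'
#' Computed over the pixels where both maps are defined (non-NA), further
#' restricted by an optional domain mask.
#'
#' @param mapA,mapB numeric matrices of the same shape.
#' @param domain optional logical matrix restricting the comparison.
#' @return Pearson r.
#' @export
mapCorrelation <- function(mapA, mapB, domain = NULL) {
  if (!identical(dim(mapA), dim(mapB))) stop("map shapes differ")
  ok <- !is.na(mapA) & !is.na(mapB)
  if (!is.null(domain)) ok <- ok & domain
  a <- mapA[ok]
  b <- mapB[ok]
  if (length(a) < 3) stop("need at least 3 jointly defined pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("map correlation undefined for a constant map")
  stats::cor(a, b)
}

#' Fraction of target choices
#'
#' @param choices binary 0/1 vector (1 = classified as the target
#'   object).
#' @return mean of the vector.
#' @export
choiceFraction <- function(choices) {
  if (length(choices) == 0) stop("empty choice vector")
  mean(choices)
}

#' Consistency between regular and outline classifications
#'
#' Treats the choices on the regular (full-body) variants as ground truth
#' and scores the choices on the matched outline variants against them.
#' Confusion entries are fractions of all pairs; accuracy = TN + TP.
#'
#' @param choicesRegular,choicesOutline paired binary vectors of equal
#'   length.
#' @return list with `fractionTripodRegular`, `fractionTripodOutline`,
#'   `confusion` (named numeric: TN, FP, FN, TP) and `accuracy`.
#' @export
outlineConsistency <- function(choicesRegular, choicesOutline) {
  if (length(choicesRegular) != length(choicesOutline))
    stop("paired choice vectors must have equal length")
  tp <- mean(choicesRegular == 1 & choicesOutline == 1)
  tn <- mean(choicesRegular == 0 & choicesOutline == 0)
  fp <- mean(choicesRegular == 0 & choicesOutline == 1)
  fn <- mean(choicesRegular == 1 & choicesOutline == 0)
  list(fractionTripodRegular = mean(choicesRegular),
       fractionTripodOutline = mean(choicesOutline),
       confusion = c(TN = tn, FP = fp, FN = fn, TP = tp),
       accuracy = tn + tp)
}
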