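#' The two canonical discriminanda
#'
#' Returns the two fixed object models used throughout the synthetic
#' experiments: a 3-lobed "tripod" (one vertical lobe and two oblique ones
#' meeting at a common center, with small depth offsets so azimuth
#' rotations foreshorten it asymmetrically) and a 4-lobed "cross". The
#' construction is deterministic: repeated calls return identical models.
#'
#' @return list with elements `tripod` and `cross`, both
#'   [ObjectModel-class].
#' @export
makeCanonicalObjects <- function() {
  lobe <- function(dir, len, thick) {
    list(start = c(0, 0, 0), end = dir / sqrt(sum(dir^2)) * len,
         thickness = thick)
  }
  tripod <- objectModel(
    "tripod",
    list(lobe(c(0, 1, 0.15), 1.0, 0.22),
         lobe(c(0.9, -0.55, 0.3), 0.95, 0.22),
         lobe(c(-0.9, -0.55, -0.25), 0.95, 0.22)),
    intensity = 1)
  cross <- objectModel(
    "cross",
    list(lobe(c(0.8, 0.8, 0.2), 0.9, 0.25),
         lobe(c(-0.8, 0.8, -0.2), 0.9, 0.25),
         lobe(c(-0.8, -0.8, 0.2), 0.9, 0.25),
         lobe(c(0.8, -0.8, -0.2), 0.9, 0.25)),
    intensity = 1)
  list(tripod = tripod, cross = cross)
}

# Project the model's lobes under the azimuth rotation only: rotate the 3D
# segments about the vertical (y) axis, drop z (orthographic projection).
# Returns a matrix (x1, y1, x2, y2, r) in object units, y up. The in-plane
# rotation is applied later, after the size scale is fixed, so that roll
# does not interact with the size convention.
project_lobes <- function(model, view) {
  az <- view@azimuthDeg * pi / 180
  rot_y <- function(p) c(p[1] * cos(az) + p[3] * sin(az), p[2])
  t(vapply(model@lobes, function(lb) {
    c(rot_y(lb$start), rot_y(lb$end), lb$thickness / 2)
  }, numeric(5)))
}

#' Render a view of an object model
#'
#' Orthographically projects the model's 3D lobes under the view's azimuth
#' rotation, scales so the object's axis-aligned bounding extent (largest
#' of width/height, including lobe thickness) spans `sizeDeg * ppd`
#' pixels, then applies the in-plane rotation about the object's origin
#' (the lobe junction, anchored at the image center), the horizontal
#' shift, and rasterizes the capsules onto a black background. The size
#' scale is fixed before the in-plane rotation — a roll of the same view
#' does not change the object's physical size — so every view transform is
#' an affine map about the image center and can be inverted exactly by
#' [alignMap()]. With `style = "outline"` only the boundary band is kept
#' (see [toOutline()]).
#'
#' @param model an [ObjectModel-class].
#' @param view a [ViewParams-class].
#' @param geom a [ViewingGeometry-class] providing the degrees-per-pixel
#'   factor and frame size.
#' @param outlineThickness boundary band width in px for outline style.
#' @return grayscale image matrix in \[0, 1\].
#' @export
renderView <- function(model, view, geom = viewingGeometry(),
                       outlineThickness = 2L) {
  seg <- project_lobes(model, view)
  r <- seg[, 5]
  xmin <- min(pmin(seg[, 1], seg[, 3]) - r)
  xmax <- max(pmax(seg[, 1], seg[, 3]) + r)
  ymin <- min(pmin(seg[, 2], seg[, 4]) - r)
  ymax <- max(pmax(seg[, 2], seg[, 4]) + r)
  extent <- max(xmax - xmin, ymax - ymin)
  target_px <- view@sizeDeg * geom@ppd
  s <- target_px / extent
  nr <- geom@resH
  nc <- geom@resW
  # scaled in-plane rotation about the object origin, then the horizontal
  # shift; y flipped into row coordinates (origin at the image center)
  ip <- view@inplaneDeg * pi / 180
  rot_x <- function(x, y) (x * cos(ip) - y * sin(ip)) * s
  rot_y2 <- function(x, y) (x * sin(ip) + y * cos(ip)) * s
  shift_px <- view@hshiftDeg * geom@ppd
  px <- function(x, y) rot_x(x, y) + (nc - 1) / 2 + shift_px
  py <- function(x, y) (nr - 1) / 2 - rot_y2(x, y)
  seg_px <- cbind(px(seg[, 1], seg[, 2]), py(seg[, 1], seg[, 2]),
                  px(seg[, 3], seg[, 4]), py(seg[, 3], seg[, 4]),
                  r * s)
  lo_x <- min(pmin(seg_px[, 1], seg_px[, 3]) - seg_px[, 5])
  hi_x <- max(pmax(seg_px[, 1], seg_px[, 3]) + seg_px[, 5])
  lo_y <- min(pmin(seg_px[, 2], seg_px[, 4]) - seg_px[, 5])
  hi_y <- max(pmax(seg_px[, 2], seg_px[, 4]) + seg_px[, 5])
  if (lo_x < -0.5 || lo_y < -0.5 || hi_x > nc - 0.5 || hi_y > nr - 0.5)
    stop(sprintf(
      paste0("rendered object exceeds the %dx%d frame for view ",
             "(size=%g deg, azimuth=%g, inplane=%g, hshift=%g)"),
      nc, nr, view@sizeDeg, view@azimuthDeg, view@inplaneDeg,
      view@hshiftDeg))
  img <- cpp_render_capsules(nr, nc, seg_px, model@intensity)
  if (view@style == "outline") img <- toOutline(img, outlineThickness)
  img
}

#' Generate a random structural variant of a model
#'
#' Perturbs every lobe independently: its projected direction is rotated
#' in the image plane (about the z axis) by a signed angle drawn uniformly
#' on +/- `angleJitterDeg`, and its length is scaled by a factor drawn
#' uniformly on 1 +/- `lengthJitter`. Thickness and the common center are
#' preserved. Seeded and reproducible; zero jitter returns an identical
#' model.
#'
#' @param model an [ObjectModel-class].
#' @param spec a [StructuralVariantSpec-class].
#' @return perturbed [ObjectModel-class].
#' @export
makeStructuralVariant <- function(model, spec) {
  with_seed(spec@seed, {
    lobes <- lapply(model@lobes, function(lb) {
      ang <- runif(1, -spec@angleJitterDeg, spec@angleJitterDeg) * pi / 180
      lenf <- 1 + runif(1, -spec@lengthJitter, spec@lengthJitter)
      v <- lb$end - lb$start
      rot <- c(v[1] * cos(ang) - v[2] * sin(ang),
               v[1] * sin(ang) + v[2] * cos(ang), v[3])
      list(start = lb$start, end = lb$start + rot * lenf,
           thickness = lb$thickness)
    })
    objectModel(paste0(model@objectId, "_variant"), lobes,
                model@intensity)
  })
}

#' Reduce a filled object image to its outline
#'
#' Keeps only the boundary band of the filled region: foreground pixels
#' with a background pixel within Chebyshev distance `thickness` retain
#' their intensity, interior pixels are set to the background (0).
#'
#' @param image filled object on a black background.
#' @param thickness boundary band width in pixels (default 2).
#' @return outline image.
#' @export
toOutline <- function(image, thickness = 2L) {
  assert_image(image)
  mask <- image > 0
  if (!any(mask)) stop("toOutline: empty image")
  t <- as.integer(thickness)
  nr <- nrow(mask)
  nc <- ncol(mask)
  # box erosion: a pixel survives if the whole (2t+1)^2 neighborhood is
  # foreground (frame treated as background)
  eroded <- mask
  padded <- matrix(FALSE, nr + 2L * t, nc + 2L * t)
  padded[(t + 1L):(t + nr), (t + 1L):(t + nc)] <- mask
  for (di in -t:t) {
    for (dj in -t:t) {
      if (di == 0L && dj == 0L) next
      eroded <- eroded &
        padded[(t + 1L + di):(t + nr + di), (t + 1L + dj):(t + nc + dj)]
    }
  }
  out <- image
  out[eroded] <- 0
  out
}

#' Simulate trial-by-trial responses of a synthetic observer
#'
#' Produces binary labels for a list of trials. Each trial is a list with
#' an `image` and optionally a `mask` (occlusion transparency in \[0, 1\])
#' and a `truth` (1-based index of the correct class).
#'
#' Observer kinds:
#' \describe{
#'   \item{template}{`params$templates` is a list of two class templates.
#'     The choice is the class with the larger dot product; with
#'     probability `lapseRate` it is replaced by a fair coin. The returned
#'     label is 1 if the choice matches `truth` (when provided), else 1
#'     when the first template is chosen.}
#'   \item{planted_feature}{`params$pixels` (logical matrix) and
#'     `params$threshold`: the label is 1 ("correct") iff the mean mask
#'     value over the planted pixels exceeds the threshold. A missing mask
#'     counts as fully transparent (m = 1).}
#'   \item{ideal_observer}{`params$observer` is an
#'     [IdealObserver-class]; the label is 1 iff the classified label
#'     equals `params$targetLabel`. Lapses as for the template kind.}
#' }
#'
#' @param responder a [ResponderSpec-class].
#' @param trials list of trial lists (see above).
#' @param seed optional integer seed.
#' @return integer vector of 0/1 labels, one per trial.
#' @export
simulateResponses <- function(responder, trials, seed = NULL) {
  with_seed(seed, {
    lam <- responder@lapseRate
    p <- responder@params
    vapply(trials, function(tr) {
      img <- if (is.list(tr)) tr$image else tr
      switch(responder@kind,
        template = {
          dots <- vapply(p$templates, function(tp) sum(tp * img), 0)
          choice <- which.max(dots)
          if (lam > 0 && runif(1) < lam) choice <- sample(1:2, 1)
          if (is.list(tr) && !is.null(tr$truth))
            as.integer(choice == tr$truth)
          else as.integer(choice == 1L)
        },
        planted_feature = {
          m <- if (is.list(tr) && !is.null(tr$mask)) tr$mask else
            matrix(1, nrow(img), ncol(img))
          as.integer(mean(m[p$pixels]) > p$threshold)
        },
        ideal_observer = {
          lab <- idealObserverClassify(img, p$observer)
          ok <- as.integer(lab == p$targetLabel)
          if (lam > 0 && runif(1) < lam) ok <- sample(0:1, 1)
          ok
        },
        stop("unknown responder kind: ", responder@kind))
    }, integer(1))
  })
}

#' Render a batch of structural variants
#'
#' Convenience generator for the structural-variant experiments: draws `n`
#' random variants of `model` (seeds derived from `seed`), renders each
#' under `view`, and returns both the images and the variant models.
#'
#' @param model target [ObjectModel-class].
#' @param n number of variants.
#' @param view a [ViewParams-class] (its `style` is honored).
#' @param geom a [ViewingGeometry-class].
#' @param angleJitterDeg,lengthJitter jitter magnitudes.
#' @param seed integer seed.
#' @return list with `images` (list of matrices) and `models`.
#' @export
renderVariantSet <- function(model, n, view = viewParams(),
                             geom = viewingGeometry(),
                             angleJitterDeg = 20, lengthJitter = 0.2,
                             seed = 1L) {
  seeds <- with_seed(seed, sample.int(2147483646L, n))
  models <- lapply(seeds, function(s) {
    makeStructuralVariant(model, structuralVariantSpec(
      angleJitterDeg = angleJitterDeg, lengthJitter = lengthJitter,
      seed = s))
  })
  images <- lapply(models, renderView, view = view, geom = geom)
  list(images = images, models = models)
}
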