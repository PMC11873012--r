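# Shared fixtures: a small rendering geometry keeps unit tests fast while
# preserving the standard pixels-per-degree factor, and a coarse "desk"
# geometry (full 96-degree span at 64 px) is used where whole-object views
# must fit in a small frame.

geom_small <- function() {
  viewingGeometry(resW = 96L, resH = 96L)
}

geom_desk <- function(res = 64L) {
  viewingGeometry(resW = res, resH = res, ppd = res / 96)
}

geom_csf <- function() {
  viewingGeometry(resW = 112L, resH = 112L)
}

tripod_model <- function() makeCanonicalObjects()$tripod
cross_model <- function() makeCanonicalObjects()$cross

# bounding-box extent (max of height/width) of the nonzero region, px
bbox_extent <- function(img, thr = 0) {
  m <- img > thr
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  max(diff(range(rows)), diff(range(cols))) + 1L
}

# centered disk mask
disk_mask <- function(side, radius, cx = (side + 1) / 2, cy = (side + 1) / 2) {
  xs <- matrix(rep(seq_len(side), each = side), side)
  ys <- matrix(rep(seq_len(side), side), side)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 0 else sum(a & b) / u
}
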