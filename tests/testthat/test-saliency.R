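# Bubble masks, the two classification-image estimators and their
# permutation tests, and the ideal observer.

test_that("bubble masks respect their construction rules", {
  geom <- viewingGeometry()
  spec <- bubbleMaskSpec(geom = geom)
  # FWHM convention: 2 deg * ppd px, within 5% on a rendered bubble
  m1 <- makeBubbleMasks(1, bubbleMaskSpec(nBubbles = 1, geom = geom),
                        224, seed = 3)
  img <- maskAsMatrix(m1, 1)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  prof <- img[pk[1], ]
  fwhm <- sum(prof >= max(img) / 2)
  expect_lt(abs(fwhm - 2 * geom@ppd) / (2 * geom@ppd), 0.1)
  # no bubbles -> all-zero mask; values clipped to [0, 1]
  m0 <- makeBubbleMasks(1, bubbleMaskSpec(nBubbles = 0, geom = geom), 64)
  expect_true(all(m0 == 0))
  mm <- makeBubbleMasks(20, spec, 64, seed = 5)
  expect_true(all(mm >= 0 & mm <= 1))
  # coverage grows with the number of bubbles (10 -> 40 -> 90)
  cov <- vapply(c(10, 40, 90), function(nb) {
    mean(makeBubbleMasks(200, bubbleMaskSpec(nBubbles = nb, geom = geom),
                         64, seed = nb))
  }, numeric(1))
  expect_true(all(diff(cov) > 0))
  # centers stay inside the central 70% square: outside corners uncovered
  big <- makeBubbleMasks(200, spec, 224, seed = 6)
  corner <- colSums(big)[1:3]
  expect_true(all(corner < 1e-6))
})

test_that("alpha masking is a convex combination with black background", {
  img <- matrix(0.8, 4, 4)
  expect_equal(applyMask(img, matrix(1, 4, 4)), img)
  expect_true(all(applyMask(img, matrix(0, 4, 4)) == 0))
  expect_equal(applyMask(matrix(0.8, 1, 1), matrix(0.5, 1, 1))[1, 1], 0.4)
  expect_error(applyMask(img, matrix(1, 3, 3)), "differ")
})

test_that("the bubbles estimator satisfies its identities", {
  set.seed(20)
  masks <- makeBubbleMasks(50, bubbleMaskSpec(), 16, seed = 1)
  # all-correct -> 1 on covered pixels; all-wrong -> 0
  s1 <- bubblesSaliency(masks, rep(1, 50))
  expect_true(all(abs(s1$S[s1$covered] - 1) < 1e-12))
  s0 <- bubblesSaliency(masks, rep(0, 50))
  expect_true(all(abs(s0$S[s0$covered]) < 1e-12))
  # two-trial hand example at one pixel: m = (1, 0.5), l = (1, 0)
  m2 <- rbind(c(1, 0, 0, 0), c(0.5, 0, 0, 0))
  s2 <- bubblesSaliency(m2, c(1, 0))
  expect_equal(s2$S[1, 1], 1 / 1.5, tolerance = 1e-9)
  expect_true(is.na(s2$S[2, 1])) # never covered
  # duplication invariance
  lab <- sample(0:1, 50, replace = TRUE)
  sa <- bubblesSaliency(masks, lab)
  sb <- bubblesSaliency(rbind(masks, masks), c(lab, lab))
  expect_equal(sa$S, sb$S)
  expect_error(bubblesSaliency(masks[0, , drop = FALSE], integer(0)))
})

test_that("bubbles permutation test is calibrated and disjoint", {
  set.seed(21)
  side <- 64L
  masks <- makeBubbleMasks(300, bubbleMaskSpec(), side, seed = 2)
  labels <- sample(0:1, 300, replace = TRUE) # independent of the masks
  map <- permutationSignificanceBubbles(masks, labels, nPerm = 400L,
                                        pTh = 0.05, seed = 3)
  ncov <- sum(map@covered)
  expect_lt(abs(sum(salientMask(map)) / ncov - 0.05), 0.025)
  expect_lt(abs(sum(antisalientMask(map)) / ncov - 0.05), 0.025)
  expect_false(any(salientMask(map) & antisalientMask(map)))
  expect_error(permutationSignificanceBubbles(masks, rep(1, 300)),
               "both label")
})

test_that("area-matched thresholds hit the requested region size", {
  set.seed(22)
  side <- 64L # corners lie outside the 70% bubble region -> never covered
  masks <- makeBubbleMasks(400, bubbleMaskSpec(), side, seed = 4)
  labels <- sample(0:1, 400, replace = TRUE) # random map
  res <- permutationSignificanceBubbles(masks, labels, nPerm = 300L,
                                        seed = 5, returnNull = TRUE)
  obs <- bubblesSaliency(masks, labels)
  # target 0 -> empty region
  m0 <- areaMatchedThreshold(obs, res$null, 0)
  expect_equal(sum(salientMask(m0)), 0)
  # a reachable target is met within tolerance
  target <- 150
  mt <- areaMatchedThreshold(obs, res$null, target, tol = 1)
  expect_lte(abs(sum(salientMask(mt)) - target), 1)
  # self-consistency: using the p = 0.05 region's own area recovers p
  a05 <- sum(salientMask(res$map))
  if (a05 > 0) {
    m05 <- areaMatchedThreshold(obs, res$null, a05, tol = 1)
    expect_lt(abs(m05@pThreshold - 0.05), 0.05)
  }
  expect_error(areaMatchedThreshold(obs, res$null, side^2), "unreachable")
})

test_that("ideal observer matches brute-force template matching", {
  geom <- geom_desk()
  models <- makeCanonicalObjects()
  views <- lapply(c(0, 30), function(az)
    viewParams(sizeDeg = 60, azimuthDeg = az))
  obs <- buildIdealObserver(models, views, geom)
  expect_length(obs@templates, 4)
  # a stored template classifies as its own label
  expect_equal(idealObserverClassify(obs@templates[[1]], obs),
               "tripod")
  # ties break toward the lowest template index
  tie_obs <- idealObserver(list(matrix(1, 2, 2), matrix(1, 2, 2)),
                           c("first", "second"))
  expect_equal(idealObserverClassify(matrix(1, 2, 2), tie_obs), "first")
  # occluded inputs match explicit dot-product enumeration
  set.seed(23)
  masks <- makeBubbleMasks(20, bubbleMaskSpec(geom = geom), 64, seed = 6)
  for (i in 1:20) {
    img <- applyMask(obs@templates[[sample(4, 1)]], maskAsMatrix(masks, i))
    dots <- vapply(obs@templates, function(tp) sum(tp * img), 0)
    expect_equal(idealObserverClassify(img, obs),
                 obs@labels[which.max(dots)])
  }
})

test_that("the structural-variant estimator is a conditional-mean difference", {
  set.seed(24)
  t1 <- matrix(runif(64), 8)
  t0 <- matrix(runif(64), 8)
  s <- tripodSaliency(rbind(as.numeric(t1), as.numeric(t0)), c(1, 0))
  expect_equal(s$S, t1 - t0)
  expect_error(tripodSaliency(rbind(as.numeric(t1), as.numeric(t0)),
                              c(1, 1)), "empty")
  # choices independent of the images -> map within 3 SE of zero
  n <- 400
  trials <- matrix(runif(n * 64), n)
  r <- sample(0:1, n, replace = TRUE)
  s0 <- tripodSaliency(trials, r)
  se <- sqrt(1 / 12) * sqrt(1 / sum(r == 1) + 1 / sum(r == 0))
  expect_true(mean(abs(s0$S) < 3 * se) > 0.99)
})

test_that("variant permutation test is calibrated with a Gaussian null", {
  set.seed(25)
  n <- 300
  trials <- matrix(runif(n * 32 * 32), n)
  r <- sample(0:1, n, replace = TRUE)
  map <- permutationSignificanceTripod(trials, r, nPerm = 100L,
                                       pTh = 0.01, seed = 7)
  frac_hi <- sum(salientMask(map)) / length(salientMask(map))
  frac_lo <- sum(antisalientMask(map)) / length(antisalientMask(map))
  expect_lt(abs(frac_hi - 0.01), 0.011)
  expect_lt(abs(frac_lo - 0.01), 0.011)
  expect_false(any(salientMask(map) & antisalientMask(map)))
})
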