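# Procedural object stimuli and simulated observers.

test_that("canonical objects are fixed, distinct and deterministic", {
  a <- makeCanonicalObjects()
  b <- makeCanonicalObjects()
  expect_length(a$tripod@lobes, 3)
  expect_false(length(a$tripod@lobes) == length(a$cross@lobes))
  expect_identical(a, b)
})

test_that("rendered views obey the size convention", {
  geom <- viewingGeometry()
  img <- renderView(tripod_model(), viewParams(sizeDeg = 35), geom)
  expect_true(all(img >= 0 & img <= 1))
  # 35 deg at 224/96 px/deg spans ~82 px
  expect_lte(abs(bbox_extent(img) - 35 * geom@ppd), 1)
  # doubling the size doubles the extent within a pixel
  img2 <- renderView(tripod_model(), viewParams(sizeDeg = 70), geom)
  expect_lte(abs(bbox_extent(img2) - 2 * bbox_extent(img)), 2)
  # background is exactly zero before augmentation
  expect_identical(sort(unique(as.numeric(img))), c(0, 1))
  # an oversized view errors, naming the offending view
  expect_error(renderView(tripod_model(), viewParams(sizeDeg = 200), geom),
               "size=200")
})

test_that("rendering is equivariant under horizontal shift", {
  geom <- viewingGeometry()
  base <- renderView(tripod_model(), viewParams(), geom)
  shifted <- renderView(tripod_model(), viewParams(hshiftDeg = 6), geom)
  translated <- applyAffine(base,
                            augmentationSample(0, 6 * geom@ppd / geom@resW,
                                               0))
  m1 <- shifted > 0.5
  m2 <- translated > 0.5
  expect_gte(iou(m1, m2), 0.95)
})

test_that("azimuth rotation foreshortens via 3D projection", {
  geom <- viewingGeometry()
  base <- renderView(tripod_model(), viewParams(), geom)
  rot <- renderView(tripod_model(), viewParams(azimuthDeg = 60), geom)
  expect_false(isTRUE(all.equal(base, rot)))
  # identity transform reproduces the canonical projection
  again <- renderView(tripod_model(), viewParams(azimuthDeg = 0), geom)
  expect_identical(base, again)
})

test_that("structural variants are seeded and jitter-calibrated", {
  m <- tripod_model()
  # zero jitter returns the model unchanged
  v0 <- makeStructuralVariant(m, structuralVariantSpec(0, 0, seed = 5))
  for (l in seq_along(m@lobes))
    expect_equal(v0@lobes[[l]]$end, m@lobes[[l]]$end)
  # same seed -> identical variant
  v1 <- makeStructuralVariant(m, structuralVariantSpec(20, 0.2, seed = 9))
  v2 <- makeStructuralVariant(m, structuralVariantSpec(20, 0.2, seed = 9))
  expect_identical(v1, v2)
  # the signed in-plane angle deviation is uniform on +/- 20 degrees
  angle_dev <- function(variant, lobe) {
    a <- m@lobes[[lobe]]$end
    b <- variant@lobes[[lobe]]$end
    (atan2(b[2], b[1]) - atan2(a[2], a[1])) * 180 / pi
  }
  devs <- unlist(lapply(1:1000, function(s) {
    v <- makeStructuralVariant(m, structuralVariantSpec(20, 0, seed = s))
    vapply(1:3, function(l) angle_dev(v, l), 0)
  }))
  devs <- ((devs + 180) %% 360) - 180
  expect_gt(stats::ks.test(devs, "punif", -20, 20)$p.value, 0.01)
  # jitter -> 0 converges to the base model in image space
  geom <- viewingGeometry()
  base <- renderView(m, viewParams(), geom)
  small <- renderView(
    makeStructuralVariant(m, structuralVariantSpec(0.1, 0.001, seed = 3)),
    viewParams(), geom)
  expect_lt(mean(abs(base - small)), 0.02)
})

test_that("outline extraction keeps only the boundary band", {
  side <- 101L
  disk <- matrix(0, side, side)
  disk[disk_mask(side, 30)] <- 1
  ring <- toOutline(disk, 2L)
  expect_true(any(ring > 0))
  # interior removed: center pixel black, boundary retained
  expect_equal(ring[51, 51], 0)
  m_ring <- ring > 0
  # every ring pixel lies near the disk boundary
  rad <- sqrt((row(ring)[m_ring] - 51)^2 + (col(ring)[m_ring] - 51)^2)
  expect_true(all(rad > 27 & rad <= 30.5))
  # outline of the outline is a subset of the outline
  ring2 <- toOutline(ring, 2L)
  expect_true(all(which(ring2 > 0) %in% which(ring > 0)))
  # outline is dimmer than the filled version overall
  expect_lt(mean(ring), mean(disk))
  expect_error(toOutline(matrix(0, 5, 5)), "empty")
})

test_that("outline views reduce mean luminance of rendered objects", {
  geom <- viewingGeometry()
  filled <- renderView(tripod_model(), viewParams(), geom)
  outline <- renderView(tripod_model(),
                        viewParams(style = "outline"), geom)
  expect_lt(mean(outline), mean(filled))
})

test_that("simulated responders implement their contracts", {
  geom <- geom_desk()
  t1 <- renderView(tripod_model(), viewParams(), geom)
  t2 <- renderView(cross_model(), viewParams(), geom)
  tmpl <- responderSpec("template", 0, list(templates = list(t1, t2)))
  # lambda = 0, shown its own template -> always correct
  trials <- replicate(20, list(image = t1, truth = 1), simplify = FALSE)
  expect_true(all(simulateResponses(tmpl, trials, seed = 1) == 1))
  # lambda = 1 -> long-run accuracy is chance (binomial CI at n = 10000)
  lapser <- responderSpec("template", 1, list(templates = list(t1, t2)))
  trials <- replicate(10000, list(image = t1, truth = 1), simplify = FALSE)
  acc <- mean(simulateResponses(lapser, trials, seed = 2))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)
  # planted feature with a fully transparent mask is always correct
  planted <- responderSpec("planted_feature", 0,
                           list(pixels = disk_mask(64, 5),
                                threshold = 0.5))
  trials <- replicate(10, list(image = t1), simplify = FALSE)
  expect_true(all(simulateResponses(planted, trials) == 1))
  # unknown kind errors at construction
  expect_error(responderSpec("nonsense"))
  # seeded reproducibility
  lap <- responderSpec("template", 0.5, list(templates = list(t1, t2)))
  trials <- replicate(50, list(image = t1, truth = 1), simplify = FALSE)
  expect_identical(simulateResponses(lap, trials, seed = 7),
                   simulateResponses(lap, trials, seed = 7))
})
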