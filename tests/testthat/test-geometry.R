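# Head-pose geometry and the blur/noise front end.

test_that("angular displacement follows the tangent rule and is odd", {
  expect_equal(angularDisplacement(0, 30), 0)
  expect_equal(angularDisplacement(60, 30), 34.64, tolerance = 1e-3)
  expect_equal(angularDisplacement(20, 30), 10.58, tolerance = 1e-3)
  # oddness and monotonicity
  thetas <- seq(5, 175, by = 10)
  expect_equal(angularDisplacement(-thetas, 30),
               -angularDisplacement(thetas, 30))
  expect_true(all(diff(angularDisplacement(thetas, 30)) > 0))
  expect_error(angularDisplacement(180, 30))
})

test_that("displacement fraction is the uniform half-width", {
  expect_equal(displacementFraction(0, 48), 0)
  expect_equal(displacementFraction(10.58, 48), 0.110, tolerance = 1e-2)
  expect_equal(displacementFraction(34.64, 27), 0.641, tolerance = 1e-2)
})

test_that("head-pose sampler respects the printed spans and is seeded", {
  ranges <- headPoseRanges() # 60 / 35 / 20
  geom <- viewingGeometry()
  xmax <- displacementFraction(angularDisplacement(20, 30), 48)
  ymax <- displacementFraction(angularDisplacement(60, 30), 27)
  set.seed(7)
  draws <- replicate(500, {
    s <- sampleHeadPose(ranges, geom)
    c(s@alphaDeg, s@xFrac, s@yFrac)
  })
  expect_true(all(abs(draws[1, ]) <= 17.5))
  expect_true(all(abs(draws[2, ]) <= xmax + 1e-12))
  expect_true(all(abs(draws[3, ]) <= ymax + 1e-12))
  # roll is uniform over +/- 17.5 degrees
  expect_gt(stats::ks.test(draws[1, ], "punif", -17.5, 17.5)$p.value, 0.01)
  # zero spans give the identity sample
  s0 <- sampleHeadPose(headPoseRanges(0, 0, 0), geom, seed = 1)
  expect_equal(c(s0@alphaDeg, s0@xFrac, s0@yFrac), c(0, 0, 0))
  # determinism
  s1 <- sampleHeadPose(ranges, geom, seed = 42)
  s2 <- sampleHeadPose(ranges, geom, seed = 42)
  expect_identical(s1, s2)
})

test_that("affine warp rotates about the center and round-trips", {
  # symmetric bar at the exact center of an even-sized frame
  bar <- matrix(0, 100, 100)
  bar[49:52, 21:80] <- 1
  rot <- applyAffine(bar, augmentationSample(90, 0, 0))
  vert <- matrix(0, 100, 100)
  vert[21:80, 49:52] <- 1
  expect_gte(iou(rot > 0.5, vert > 0.5), 0.9)
  # identity sample leaves the image unchanged
  expect_equal(applyAffine(bar, augmentationSample(0, 0, 0)), bar)
  # translation round trip on interior pixels
  img <- renderView(tripod_model(), viewParams(), viewingGeometry())
  rt <- applyAffine(applyAffine(img, augmentationSample(0, 0.1, 0)),
                    augmentationSample(0, -0.1, 0))
  inner <- 30:190
  expect_lt(mean(abs(rt[inner, inner] - img[inner, inner])), 0.02)
})

test_that("blur/noise front end matches its declared statistics", {
  img <- matrix(0.5, 224, 224)
  # identity when both sigmas vanish
  expect_equal(applyBlurNoise(img, noiseBlurParams(0, 0), seed = 1), img)
  # blur of a constant is the constant
  expect_equal(applyBlurNoise(img, noiseBlurParams(3, 0), seed = 1), img)
  # noise SD on mid-gray is the requested SD (clipping negligible there)
  out <- applyBlurNoise(img, noiseBlurParams(0, 0.1), seed = 5)
  expect_equal(stats::sd(as.numeric(out)), 0.1, tolerance = 0.01)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("full augmentation is the identity at zero settings and seeded", {
  cfg0 <- augmentationConfig(headPoseRanges(0, 0, 0), viewingGeometry(),
                             noiseBlurParams(0, 0))
  img <- renderView(tripod_model(), viewParams(), viewingGeometry())
  expect_lt(max(abs(augment(img, cfg0, seed = 3) - img)), 1e-8)
  cfg <- augmentationConfig(noiseBlur = noiseBlurParams(1, 0.05))
  a1 <- augment(img, cfg, seed = 9)
  a2 <- augment(img, cfg, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_identical(dim(a1), dim(img))
})

test_that("augmented in-plane rotations are uniform over the roll span", {
  cfg <- augmentationConfig()
  set.seed(11)
  alphas <- replicate(1000, sampleHeadPose(cfg@ranges, cfg@geom)@alphaDeg)
  expect_gt(stats::ks.test(alphas, "punif", -17.5, 17.5)$p.value, 0.01)
})
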