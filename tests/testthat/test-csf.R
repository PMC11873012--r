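# Grating synthesis, patch-contrast features, psychometrics and the CSF
# machinery (the expensive grid-search properties live in the acceptance
# suite).

test_that("gratings follow the luminance model", {
  geom <- viewingGeometry()
  # zero contrast is uniform mid-gray
  g0 <- makeGrating(gratingSpec(0.1, 0), geom)
  expect_true(all(g0 == 0.5))
  # full contrast spans [0, 1]
  g1 <- makeGrating(gratingSpec(0.2, 1), geom)
  expect_lt(min(g1), 0.01)
  expect_gt(max(g1), 0.99)
  expect_equal(mean(g1), 0.5, tolerance = 0.01)
  # spatial period: 0.5 cyc/deg at ppd 2.333 -> 4.667 px, so the pattern
  # repeats exactly every 3 periods = 14 px along the orientation axis
  g <- makeGrating(gratingSpec(0.5, 1, orientation = 0), geom)
  expect_equal(g[1, 1:50], g[1, 1:50 + 14], tolerance = 1e-9)
  # frequencies beyond Nyquist are rejected
  expect_error(makeGrating(gratingSpec(2, 0.5), geom), "Nyquist")
})

test_that("patch contrasts are population SDs on a centered grid", {
  # uniform image -> all-zero features
  expect_true(all(patchContrasts(matrix(0.3, 56, 56), 28) == 0))
  # 224 image with p = 28 -> 64 patches
  expect_length(patchContrasts(matrix(runif(224^2), 224), 28), 64)
  # patches tiled with {0.4, 0.6} have population SD exactly 0.1
  img <- matrix(rep(c(0.4, 0.6), length.out = 56 * 56), 56, 56)
  expect_equal(patchContrasts(img, 28), rep(0.1, 4))
  expect_error(patchContrasts(matrix(0, 10, 10), 28), "larger")
})

test_that("contrast threshold interpolates in log-contrast", {
  # hand-derived crossing: midpoint in log space
  pc <- psychometricCurve(c(0.1, 0.4), c(0.2, 0.8))
  expect_equal(contrastThreshold(pc), 10^((log10(0.1) + log10(0.4)) / 2),
               tolerance = 1e-9)
  # saturated curve -> lowest tested contrast
  expect_equal(contrastThreshold(psychometricCurve(c(0.1, 0.4),
                                                   c(0.9, 0.95))), 0.1)
  # never reaching 0.5 -> infinite threshold, sensitivity 0
  expect_identical(contrastThreshold(psychometricCurve(c(0.1, 0.4),
                                                       c(0.1, 0.4))), Inf)
})

test_that("the detection observer separates visible gratings from gray", {
  geom <- geom_csf()
  det <- trainDetectionObserver(0.1, noiseBlurParams(0, 0.02), 28L, 300L,
                                geom = geom, seed = 1)
  # easiest contrast -> near-perfect detection
  hi <- detectionProbability(det, 0.1, 1, nTrials = 50, seed = 2)
  expect_gte(hi$p, 0.95)
  # zero contrast -> false-alarm-matched baseline, well below 0.5
  fa <- detectionProbability(det, 0.1, 0, nTrials = 100, seed = 3)
  expect_lt(fa$p, 0.25)
  # psychometric is monotone in contrast up to noise
  pc <- measurePsychometric(det, nTrials = 20, seed = 4)
  expect_gt(stats::cor(pc@pDetect, seq_along(pc@pDetect),
                       method = "spearman"), 0)
  # determinism under a fixed seed
  p1 <- detectionProbability(det, 0.1, 0.05, nTrials = 30, seed = 9)
  p2 <- detectionProbability(det, 0.1, 0.05, nTrials = 30, seed = 9)
  expect_identical(p1, p2)
})

test_that("extreme blur removes high-frequency sensitivity", {
  geom <- geom_csf()
  csf <- computeCSF(noiseBlurParams(6, 0.1), 28L, nuGrid = c(0.631, 1.0),
                    geom = geom, nPerClass = 300L, nTrials = 10L,
                    seed = 5)
  expect_equal(sensitivity(csf), c(0, 0))
})

test_that("sensitivity does not increase with noise", {
  geom <- geom_csf()
  sens <- vapply(c(0.05, 0.2, 0.8), function(sn) {
    csf <- computeCSF(noiseBlurParams(1, sn), 28L, nuGrid = 0.1,
                      geom = geom, nPerClass = 300L, nTrials = 15L,
                      seed = 21)
    sensitivity(csf)
  }, numeric(1))
  # allow small sampling error between adjacent levels
  expect_true(all(diff(sens) < 0.15 * pmax(sens[-3], 1)))
  expect_gt(sens[1], sens[3])
})

test_that("fitCSF bookkeeping is internally consistent", {
  geom <- geom_csf()
  target <- ratCSFStandin(nuGrid = c(0.1, 0.398))
  fit <- fitCSF(target, sigmaBlurGrid = 1, sigmaNoiseGrid = 0.1,
                patchSizes = 28L, geom = geom, nPerClass = 200L,
                nTrials = 8L, seed = 6)
  # single-cell grid returns that cell and l1 equals the landscape min
  expect_equal(fit@sigmaBlur, 1)
  expect_equal(fit@sigmaNoise, 0.1)
  expect_equal(fit@l1, min(fit@landscape))
  expect_equal(fit@l1,
               sum(abs(sensitivity(fit@bestCSF) - sensitivity(target))))
})

test_that("the rat CSF stand-in matches its printed descriptors", {
  fine <- 10^seq(log10(0.04), 0, length.out = 101)
  csf <- ratCSFStandin(nuGrid = fine)
  s <- sensitivity(csf)
  expect_equal(fine[which.max(s)], 0.1, tolerance = 0.02)
  expect_equal(s[1], 0)
  expect_equal(s[101], 0)
  # unimodal on the log-frequency axis
  d <- diff(s)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  # peak estimator recovers the peak from the smooth curve
  expect_equal(csfPeakFrequency(csf), 0.1, tolerance = 0.01)
})
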