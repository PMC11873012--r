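# End-to-end experiment pipelines at miniature scale. A cheap activation
# provider (noisy pixel projections whose SNR grows with layer index)
# stands in for a real network so the orchestration logic stays fast.

toy_provider <- function(nFeatures = 40L, noise = 2) {
  projection <- NULL
  function(images, layerId) {
    X <- do.call(rbind, lapply(images, function(im) {
      v <- as.numeric(im)
      idx <- round(seq(1, length(v), length.out = nFeatures))
      v[idx]
    }))
    snr <- layerId / 4
    X * snr + matrix(rnorm(length(X), sd = noise), nrow = nrow(X))
  }
}

tiny_profile <- list(nTrain = 120L, nTest = 120L, nMasks = 80L,
                     nRuns = 2L, scales = c(30))

tiny_augcfg <- function() {
  augmentationConfig(headPoseRanges(10, 10, 5), geom_desk(),
                     noiseBlurParams(0.5, 0.02))
}

test_that("transform-matrix experiment emits the full report", {
  models <- unname(makeCanonicalObjects())
  sizes <- c(25, 35)
  azimuths <- c(-30, 0, 30)
  tc <- matrix(FALSE, 2, 3)
  tc[2, ] <- TRUE # azimuth axis at default size
  tc[, 2] <- TRUE # size axis at default azimuth
  ref <- accuracyMatrix(matrix(0.7, 2, 3))
  rep1 <- runTransformMatrix(models, toy_provider(), layers = c(2, 6),
                             reference = ref, sizes = sizes,
                             azimuths = azimuths, trainCells = tc,
                             augcfg = tiny_augcfg(),
                             profile = tiny_profile, seed = 31)
  # layers x runs x scales accuracy matrices
  expect_length(rep1@artifacts$accuracy, 2 * 2 * 1)
  expect_equal(dim(rep1@artifacts$l1), c(2L, 1L, 2L))
  expect_equal(sum(rep1@artifacts$l1Histogram), 2 * 1)
  # every accuracy is a valid AccuracyMatrix over the full grid
  a1 <- rep1@artifacts$accuracy[[1]]
  expect_s4_class(a1, "AccuracyMatrix")
  expect_equal(dim(accuracy(a1)), c(2L, 3L))
  # bit-for-bit reproducibility under the same seed
  rep2 <- runTransformMatrix(models, toy_provider(), layers = c(2, 6),
                             reference = ref, sizes = sizes,
                             azimuths = azimuths, trainCells = tc,
                             augcfg = tiny_augcfg(),
                             profile = tiny_profile, seed = 31)
  expect_equal(rep1@artifacts$l1, rep2@artifacts$l1)
  # missing on/off-cross designation fails loudly
  expect_error(runTransformMatrix(models, toy_provider(), layers = 2,
                                  reference = ref, sizes = sizes,
                                  azimuths = azimuths, trainCells = NULL),
               "trainCells")
})

test_that("self-comparison gives L1 = 0 and Pearson = 1 per layer", {
  models <- unname(makeCanonicalObjects())
  tc <- matrix(TRUE, 2, 2)
  rep1 <- runTransformMatrix(models, toy_provider(), layers = 6,
                             sizes = c(25, 35), azimuths = c(0, 30),
                             trainCells = tc, augcfg = tiny_augcfg(),
                             profile = tiny_profile, seed = 32)
  cand <- rep1@artifacts$accuracy[[1]]
  expect_equal(compareL1(cand, cand), 0)
  if (stats::sd(accuracy(cand)) > 0)
    expect_equal(comparePearson(cand, cand), 1)
})

test_that("occlusion experiment reports accuracy, saliency and baseline", {
  models <- unname(makeCanonicalObjects())
  geom <- geom_desk()
  views <- list(viewParams(sizeDeg = 50),
                viewParams(sizeDeg = 50, azimuthDeg = 30))
  rep1 <- runOcclusion(models, toy_provider(), layerId = 6, views = views,
                       sizes = c(40, 50), azimuths = c(0, 30),
                       inplanes = 0, hshifts = 0,
                       bubbleSpec = bubbleMaskSpec(geom = geom),
                       augcfg = tiny_augcfg(),
                       profile = tiny_profile, nPerm = 50L, seed = 33)
  arts <- rep1@artifacts
  # one saliency map per object x view
  expect_length(arts$saliency, length(models) * length(views))
  expect_s4_class(arts$saliency[[1]], "SaliencyMap")
  expect_true(is.data.frame(arts$accuracy))
  expect_true(all(c("occluded", "object", "correct") %in%
                    names(arts$accuracy)))
  expect_s4_class(arts$pixelBaseline, "AccuracyMatrix")
  expect_type(arts$degenerate, "logical")
})

test_that("variants experiment with a sharply tuned observer rejects most variants", {
  geom <- geom_desk()
  models <- makeCanonicalObjects()
  target <- models$tripod
  # sharply tuned responder: choice = "tripod" only when the input matches
  # the exact tripod better than the generic variant cloud
  tmpl <- renderView(target, viewParams(), geom)
  cloud <- Reduce(`+`, renderVariantSet(target, 40, viewParams(), geom,
                                        seed = 99)$images) / 40
  obs <- responderSpec("template", 0,
                       list(templates = list(tmpl, cloud)))
  rep1 <- runVariants(target, list(models$cross), observer = obs,
                      nVariants = 150L, angleJitterDeg = 25,
                      view = viewParams(), augcfg = tiny_augcfg(),
                      profile = tiny_profile, nPerm = 40L, seed = 34)
  arts <- rep1@artifacts
  expect_length(arts$choiceRegular, 150)
  expect_length(arts$choiceOutline, 150)
  # a sharply tuned template rejects the majority of random variants
  expect_lt(arts$fractionRegular, 0.6)
  expect_s4_class(arts$saliencyRegular, "SaliencyMap")
  expect_s4_class(arts$saliencyOutline, "SaliencyMap")
  expect_true(is.numeric(arts$styleCorrelation))
  expect_equal(arts$consistency$accuracy,
               mean(arts$choiceRegular == arts$choiceOutline))
  # identical choices would give consistency accuracy 1
  expect_equal(outlineConsistency(arts$choiceRegular,
                                  arts$choiceRegular)$accuracy, 1)
})

test_that("experiment reports are reproducible bit-for-bit", {
  geom <- geom_desk()
  target <- makeCanonicalObjects()$tripod
  tmpl <- renderView(target, viewParams(), geom)
  anti <- renderView(makeCanonicalObjects()$cross, viewParams(), geom)
  obs <- responderSpec("template", 0.2,
                       list(templates = list(tmpl, anti)))
  r1 <- runVariants(target, list(), observer = obs, nVariants = 60L,
                    augcfg = tiny_augcfg(), profile = tiny_profile,
                    nPerm = 20L, seed = 35)
  r2 <- runVariants(target, list(), observer = obs, nVariants = 60L,
                    augcfg = tiny_augcfg(), profile = tiny_profile,
                    nPerm = 20L, seed = 35)
  expect_identical(r1@artifacts$choiceRegular, r2@artifacts$choiceRegular)
  expect_identical(saliency(r1@artifacts$saliencyRegular),
                   saliency(r2@artifacts$saliencyRegular))
})
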