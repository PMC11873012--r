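# Normalization, linear readouts and accuracy-pattern comparisons.

test_that("z-scoring uses training statistics and population SD", {
  tr <- cbind(c(1, 2, 3), c(5, 5, 5), c(0, 1, 0))
  expect_message(zs <- zscoreFit(tr), "dropped 1")
  z <- zscoreApply(zs, tr)
  # closed form for column (1,2,3) with population SD
  expect_equal(z[, 1], c(-1.224745, 0, 1.224745), tolerance = 1e-5)
  # training statistics reproduce mean 0 / SD 1 on the training set
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sqrt(colMeans(z^2)), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(zscoreFit(matrix(1, 5, 3)), "degenerate")
})

test_that("linear readout reaches ceiling on separable clusters", {
  set.seed(10)
  n <- 300
  X <- rbind(matrix(rnorm(n * 20), n), matrix(rnorm(n * 20) + 3, n))
  y <- rep(c("a", "b"), each = n)
  idx <- sample(2 * n, n)
  fit <- trainReadout(X[idx, ], y[idx])
  acc <- mean(predict(fit, X[-idx, ]) == y[-idx])
  expect_gte(acc, 0.99)
  expect_error(trainReadout(X, rep("a", 2 * n)), "single class")
})

test_that("shuffled labels give chance accuracy", {
  set.seed(11)
  X <- matrix(rnorm(2000 * 10), 2000)
  y <- sample(rep(c("a", "b"), each = 1000))
  fit <- trainReadout(X[1:1000, ], y[1:1000])
  acc <- mean(predict(fit, X[1001:2000, ]) == y[1001:2000])
  expect_lt(abs(acc - 0.5), 0.03 + 3 * sqrt(0.25 / 1000))
})

test_that("per-condition evaluation is a trial-weighted partition", {
  set.seed(12)
  X <- matrix(rnorm(120 * 5), 120)
  y <- rep(c("a", "b"), 60)
  X[y == "b", 1] <- X[y == "b", 1] + 10
  fit <- trainReadout(X, y)
  cond <- data.frame(size = rep(c(10, 20, 30), each = 40))
  am <- evaluateReadout(fit, X, y, cond)
  # perfect classifier -> every cell at 1
  expect_true(all(accuracy(am) == 1))
  # overall accuracy equals the trial-weighted mean of cells
  pred <- predict(fit, X)
  cnt <- table(cond$size)
  expect_equal(sum(accuracy(am) * as.numeric(cnt)) / sum(cnt),
               mean(pred == y))
  # empty cells are reported as errors
  cond2 <- data.frame(size = factor(rep(c(10, 20), 60), c(10, 20, 30)))
  expect_error(evaluateReadout(fit, X, y, cond2), "empty")
})

test_that("L1 and Pearson comparisons satisfy their identities", {
  a <- accuracyMatrix(matrix(c(0.5, 0.6, 0.7, 0.8, 0.9, 1), 2))
  b <- accuracyMatrix(accuracy(a) - 0.1)
  expect_equal(compareL1(a, a), 0)
  expect_equal(compareL1(a, b), 0.1)
  expect_equal(compareL1(b, a), compareL1(a, b))
  expect_error(compareL1(a, accuracyMatrix(matrix(0.5, 3, 3))),
               "mismatch")
  # affine invariance and sign reversal
  expect_equal(comparePearson(a, accuracyMatrix(accuracy(a) * 0.5 + 0.1)),
               1)
  expect_equal(
    comparePearson(a, accuracyMatrix(1 - accuracy(a))), -1)
  expect_equal(comparePearson(a, a), 1)
  # brute-force covariance oracle on a 3x3 pattern
  set.seed(13)
  x <- matrix(runif(9), 3)
  y <- matrix(runif(9), 3)
  n <- 9
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(comparePearson(accuracyMatrix(x), accuracyMatrix(y)),
               num / den)
  expect_error(comparePearson(a, accuracyMatrix(matrix(0.5, 2, 3))),
               "constant")
})

test_that("extrema histograms conserve counts and break ties shallow", {
  expect_equal(extremaHistogram(c(3, 1, 2), "min"), c(0, 1, 0))
  set.seed(14)
  curves <- matrix(runif(25 * 8), 25)
  expect_equal(sum(extremaHistogram(curves, "min")), 25)
  # tie between layers 2 and 4 counted at the shallower layer
  expect_equal(extremaHistogram(c(5, 1, 5, 1), "min"), c(0, 1, 0, 0))
})

test_that("pixel baseline separates luminance-differing objects", {
  geom <- geom_desk()
  cfg <- augmentationConfig(headPoseRanges(0, 10, 5), geom,
                            noiseBlurParams(0.5, 0.02))
  objs <- makeCanonicalObjects()
  set.seed(15)
  mk <- function(n) {
    imgs <- list()
    labs <- character(0)
    for (i in seq_len(n)) {
      who <- sample(1:2, 1)
      img <- renderView(objs[[who]], viewParams(), geom)
      if (who == 2) img <- img * 0.6 # luminance cue
      imgs[[i]] <- augment(img, cfg)
      labs <- c(labs, names(objs)[who])
    }
    list(imgs = imgs, labs = labs)
  }
  tr <- mk(80)
  te <- mk(60)
  am <- pixelBaseline(tr$imgs, tr$labs, te$imgs, te$labs,
                      factor(rep("all", 60)))
  expect_gt(accuracy(am)[1], 0.9)
})

test_that("training accuracy bounds fresh-draw test accuracy", {
  set.seed(16)
  labels <- rep(c("a", "b"), each = 80)
  acts <- simulateLadderActivations(labels, runif(160, 0.2, 0.8),
                                    nLayers = 2, nUnits = 30, seed = 3)
  a <- acts[[1]]
  zs <- zscoreFit(a)
  fit <- trainReadout(zscoreApply(zs, a), labels)
  train_acc <- mean(predict(fit, zscoreApply(zs, a)) == labels)
  # fresh stimuli from an independent draw of the same process
  acts2 <- simulateLadderActivations(labels, runif(160, 0.2, 0.8),
                                     nLayers = 2, nUnits = 30, seed = 4)
  test_acc <- mean(predict(fit, zscoreApply(zs, acts2[[1]])) == labels)
  expect_gte(train_acc, test_acc - 0.02)
})
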