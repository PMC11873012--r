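#' Experiment size profiles
#'
#' Two bundles of simulation sizes: `"paper"` uses the printed counts
#' (5000 training images, 3000 masked trials per view, 5 classification
#' runs, population scales 10^3..10^5), `"desk"` shrinks them for
#' single-CPU exploratory runs.
#'
#' @param profile `"desk"` or `"paper"`.
#' @return list with `nTrain`, `nTest`, `nMasks`, `nRuns`, `scales`.
#' @export
experimentProfile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper")
    list(nTrain = 5000L, nTest = 5000L, nMasks = 3000L, nRuns = 5L,
         scales = c(1e3, 5e3, 1e4, 5e4, 1e5))
  else
    list(nTrain = 600L, nTest = 600L, nMasks = 500L, nRuns = 2L,
         scales = c(1e3, 1e4))
}

#' Linear readout observer over an activation provider
#'
#' Trains the standard readout pipeline (unit subsample, z-scoring on the
#' training set, linear SVM) on the activations of one layer and returns
#' a predictor usable as a synthetic observer.
#'
#' @param provider function(images, layerId) returning a stimulus x unit
#'   activation matrix, e.g. a closure over [extractActivations()].
#' @param trainImages list of training images.
#' @param trainLabels training class labels.
#' @param layerId probed layer.
#' @param scale requested unit-population size (capped at the layer
#'   size).
#' @param seed optional integer seed (unit sampling).
#' @return list with `predict` (function(images) -> labels), `layerId`,
#'   `unitSample`.
#' @export
readoutObserver <- function(provider, trainImages, trainLabels, layerId,
                            scale = Inf, seed = NULL) {
  acts <- provider(trainImages, layerId)
  us <- sampleUnits(ncol(acts), min(scale, ncol(acts)), layerId, seed)
  acts <- acts[, us@indices, drop = FALSE]
  zs <- zscoreFit(acts)
  fit <- trainReadout(zscoreApply(zs, acts), trainLabels)
  list(predict = function(images) {
    a <- provider(images, layerId)[, us@indices, drop = FALSE]
    as.character(predict(fit, zscoreApply(zs, a)))
  }, layerId = layerId, unitSample = us)
}

render_condition_set <- function(models, grid, n, augcfg,
                                 styles = "regular") {
  idx <- sample.int(nrow(grid), n, replace = TRUE)
  obj <- sample.int(length(models), n, replace = TRUE)
  images <- vector("list", n)
  for (t in seq_len(n)) {
    vw <- viewParams(sizeDeg = grid$size[idx[t]],
                     azimuthDeg = grid$azimuth[idx[t]],
                     inplaneDeg = grid$inplane[idx[t]],
                     hshiftDeg = grid$hshift[idx[t]],
                     style = styles[1 + (t - 1) %% length(styles)])
    img <- renderView(models[[obj[t]]], vw, augcfg@geom)
    images[[t]] <- augment(img, augcfg)
  }
  list(images = images,
       labels = vapply(models, slot, "", "objectId")[obj],
       conditions = grid[idx, , drop = FALSE])
}

full_grid <- function(sizes = 35, azimuths = 0, inplanes = 0, hshifts = 0) {
  expand.grid(size = sizes, azimuth = azimuths, inplane = inplanes,
              hshift = hshifts)
}

#' Transformation-matrix experiment
#'
#' Trains per-layer linear readouts on the on-cross cells of a size x
#' azimuth transformation matrix and evaluates them over the full matrix,
#' comparing each layer's accuracy pattern to a reference observer via L1
#' distance and Pearson correlation, with extrema histograms over runs and
#' population scales.
#'
#' @param models list of two [ObjectModel-class] objects.
#' @param provider function(images, layerId) -> activation matrix.
#' @param layers layer ids to probe.
#' @param reference optional reference [AccuracyMatrix-class] over the
#'   same size x azimuth grid.
#' @param sizes,azimuths grid axes (degrees).
#' @param trainCells logical sizes x azimuths matrix marking the on-cross
#'   (training) cells; required.
#' @param augcfg an [AugmentationConfig-class].
#' @param profile an [experimentProfile()] list.
#' @param seed integer seed.
#' @return an [ExperimentReport-class] with artifacts `accuracy` (nested
#'   per layer/run/scale), `l1`, `pearson` (run x scale x layer arrays),
#'   `l1Histogram`, `pearsonHistogram`.
#' @export
runTransformMatrix <- function(models, provider, layers,
                               reference = NULL, sizes, azimuths,
                               trainCells, augcfg = augmentationConfig(),
                               profile = experimentProfile("desk"),
                               seed = 1L) {
  if (missing(trainCells) || is.null(trainCells))
    stop("on/off-cross designation (trainCells) is required")
  stopifnot(identical(dim(trainCells),
                      c(length(sizes), length(azimuths))))
  on_idx <- which(trainCells, arr.ind = TRUE)
  on_grid <- full_grid(0, 0)[0, ]
  on_grid <- data.frame(size = sizes[on_idx[, 1]],
                        azimuth = azimuths[on_idx[, 2]],
                        inplane = 0, hshift = 0)
  all_grid <- full_grid(sizes, azimuths)
  nL <- length(layers)
  nR <- profile$nRuns
  nS <- length(profile$scales)
  l1 <- array(NA_real_, c(nR, nS, nL))
  pr <- array(NA_real_, c(nR, nS, nL))
  acc_list <- list()
  with_seed(seed, {
    for (run in seq_len(nR)) {
      train <- render_condition_set(models, on_grid, profile$nTrain,
                                    augcfg)
      test <- render_condition_set(models, all_grid, profile$nTest,
                                   augcfg)
      cond <- data.frame(size = factor(test$conditions$size, sizes),
                         azimuth = factor(test$conditions$azimuth,
                                          azimuths))
      for (si in seq_len(nS)) {
        for (li in seq_len(nL)) {
          obs <- readoutObserver(provider, train$images, train$labels,
                                 layers[li], profile$scales[si])
          pred <- obs$predict(test$images)
          correct <- pred == test$labels
          am <- accuracyMatrix(
            tapply(correct, cond, mean),
            list(layer = layers[li], run = run,
                 scale = profile$scales[si]))
          acc_list[[sprintf("layer%d_run%d_scale%g", layers[li], run,
                            profile$scales[si])]] <- am
          if (!is.null(reference)) {
            l1[run, si, li] <- compareL1(reference, am)
            # a constant candidate pattern has no defined correlation
            pr[run, si, li] <- tryCatch(comparePearson(reference, am),
                                        error = function(e) NA_real_)
          }
        }
      }
    }
  })
  arts <- list(accuracy = acc_list, l1 = l1, pearson = pr)
  if (!is.null(reference)) {
    curves_l1 <- matrix(l1, ncol = nL)
    curves_pr <- matrix(pr, ncol = nL)
    arts$l1Histogram <- extremaHistogram(curves_l1, "min")
    arts$pearsonHistogram <- extremaHistogram(curves_pr, "max")
  }
  new("ExperimentReport", experiment = "transform_matrix",
      artifacts = arts,
      provenance = list(seed = seed, layers = layers,
                        scales = profile$scales, nRuns = nR,
                        sizes = sizes, azimuths = azimuths))
}

#' Occlusion experiment
#'
#' Trains readouts on an even mixture of unoccluded and bubble-occluded
#' views of two objects across all four transformation axes, measures
#' accuracy separately for unoccluded and occluded test sets, extracts a
#' bubbles classification image for every (object, view) combination, and
#' includes the pixel-based baseline. Training without occluded images
#' tends to produce degenerate occluded-test performance (one object
#' nearly always chosen); the report flags that failure mode.
#'
#' @param models list of two [ObjectModel-class] objects.
#' @param provider function(images, layerId) -> activation matrix.
#' @param layerId probed layer.
#' @param views list of [ViewParams-class] to probe with bubbles (per
#'   object).
#' @param sizes,azimuths,inplanes,hshifts transformation axis levels for
#'   the accuracy curves.
#' @param bubbleSpec a [bubbleMaskSpec()] list.
#' @param augcfg an [AugmentationConfig-class].
#' @param occludedFraction fraction of occluded images during training
#'   (0.5 matches the reference protocol; 0 reproduces the degenerate
#'   regime).
#' @param profile an [experimentProfile()] list.
#' @param nPerm permutations for the saliency significance maps.
#' @param seed integer seed.
#' @return an [ExperimentReport-class] with artifacts `accuracy`
#'   (data.frame over axis/level/occlusion), `saliency` (named list of
#'   [SaliencyMap-class], one per object x view), `pixelBaseline`,
#'   `degenerate` (logical).
#' @export
runOcclusion <- function(models, provider, layerId, views,
                         sizes = c(25, 35), azimuths = c(-30, 0, 30),
                         inplanes = c(0, 30), hshifts = c(0, 6),
                         bubbleSpec = NULL,
                         augcfg = augmentationConfig(),
                         occludedFraction = 0.5,
                         profile = experimentProfile("desk"),
                         nPerm = 200L, seed = 1L) {
  geom <- augcfg@geom
  if (is.null(bubbleSpec)) stop("a bubble mask specification is required")
  grid <- unique(rbind(full_grid(sizes, 0, 0, 0),
                       full_grid(35, azimuths, 0, 0),
                       full_grid(35, 0, inplanes, 0),
                       full_grid(35, 0, 0, hshifts)))
  side <- geom@resH
  labels_of <- vapply(models, slot, "", "objectId")
  with_seed(seed, {
    # training pool: occludedFraction of the images get a fresh mask
    n_tr <- profile$nTrain
    occl <- runif(n_tr) < occludedFraction
    tr_masks <- makeBubbleMasks(max(sum(occl), 1L), bubbleSpec, side)
    idx <- sample.int(nrow(grid), n_tr, replace = TRUE)
    obj <- sample.int(2L, n_tr, replace = TRUE)
    mi <- 0L
    tr_images <- vector("list", n_tr)
    for (t in seq_len(n_tr)) {
      vw <- viewParams(sizeDeg = grid$size[idx[t]],
                       azimuthDeg = grid$azimuth[idx[t]],
                       inplaneDeg = grid$inplane[idx[t]],
                       hshiftDeg = grid$hshift[idx[t]])
      img <- renderView(models[[obj[t]]], vw, geom)
      if (occl[t]) {
        mi <- mi + 1L
        img <- applyMask(img, maskAsMatrix(tr_masks, mi))
      }
      tr_images[[t]] <- augment(img, augcfg)
    }
    tr_labels <- labels_of[obj]
    obs <- readoutObserver(provider, tr_images, tr_labels, layerId)

    # test pools: unoccluded and occluded, per condition
    eval_pool <- function(occluded) {
      n_te <- profile$nTest %/% 2L
      masks <- if (occluded) makeBubbleMasks(n_te, bubbleSpec, side)
      idx <- sample.int(nrow(grid), n_te, replace = TRUE)
      obj <- sample.int(2L, n_te, replace = TRUE)
      ims <- vector("list", n_te)
      for (t in seq_len(n_te)) {
        vw <- viewParams(sizeDeg = grid$size[idx[t]],
                         azimuthDeg = grid$azimuth[idx[t]],
                         inplaneDeg = grid$inplane[idx[t]],
                         hshiftDeg = grid$hshift[idx[t]])
        img <- renderView(models[[obj[t]]], vw, geom)
        if (occluded) img <- applyMask(img, maskAsMatrix(masks, t))
        ims[[t]] <- augment(img, augcfg)
      }
      pred <- obs$predict(ims)
      truth <- labels_of[obj]
      list(images = ims, labels = truth,
           res = data.frame(idx = idx, object = truth,
                            correct = pred == truth,
                            occluded = occluded))
    }
    pool_un <- eval_pool(FALSE)
    pool_oc <- eval_pool(TRUE)
    res_un <- pool_un$res
    res_oc <- pool_oc$res
    res <- rbind(res_un, res_oc)
    acc_tab <- aggregate(correct ~ occluded + object, data = res, FUN = mean)

    degenerate <- with(
      aggregate(correct ~ object, data = res_oc, FUN = mean),
      length(correct) == 2 && min(correct) < 0.1 && max(correct) > 0.9)

    # bubbles saliency per object x view
    sal <- list()
    for (m in seq_along(models)) {
      for (v in seq_along(views)) {
        base <- renderView(models[[m]], views[[v]], geom)
        masks <- makeBubbleMasks(profile$nMasks, bubbleSpec, side)
        ims <- lapply(seq_len(profile$nMasks), function(t) {
          augment(applyMask(base, maskAsMatrix(masks, t)), augcfg)
        })
        pred <- obs$predict(ims)
        lab <- as.integer(pred == labels_of[m])
        sal[[sprintf("%s_view%d", labels_of[m], v)]] <-
          permutationSignificanceBubbles(masks, lab, nPerm = nPerm)
      }
    }

    # pixel baseline on the same protocol (raw pixels as features)
    px <- pixelBaseline(
      tr_images, tr_labels,
      c(pool_un$images, pool_oc$images),
      c(pool_un$labels, pool_oc$labels),
      factor(rep(c("unoccluded", "occluded"),
                 c(length(pool_un$images), length(pool_oc$images)))))
    new("ExperimentReport", experiment = "occlusion",
        artifacts = list(accuracy = acc_tab, perTrial = res,
                         saliency = sal, degenerate = degenerate,
                         pixelBaseline = px),
        provenance = list(seed = seed, layerId = layerId,
                          occludedFraction = occludedFraction,
                          nMasks = profile$nMasks))
  })
}

#' Structural-variants experiment
#'
#' Trains an observer to discriminate a target object from a pool of
#' distractors, then probes it with random structural variants of the
#' target in both regular and outline styles (a pure generalization
#' setting: the variants were never seen in training). Reports the
#' fraction of variants classified as the target per style, the
#' difference-of-means saliency maps for both styles, their correlation,
#' and the regular-vs-outline consistency confusion matrix.
#'
#' @param target target [ObjectModel-class].
#' @param distractors list of distractor models.
#' @param observer either a [ResponderSpec-class] (classified directly)
#'   or NULL to use the readout path via `provider`/`layerId`.
#' @param provider,layerId readout path (used when `observer` is NULL).
#' @param nVariants number of random variants.
#' @param angleJitterDeg,lengthJitter variant jitter.
#' @param view base [ViewParams-class] for rendering.
#' @param augcfg an [AugmentationConfig-class]; variants are augmented
#'   before classification.
#' @param profile an [experimentProfile()] list.
#' @param nPerm,pTh significance-map settings.
#' @param seed integer seed.
#' @return an [ExperimentReport-class] with artifacts `choiceRegular`,
#'   `choiceOutline` (binary vectors), `fractionRegular`,
#'   `fractionOutline`, `saliencyRegular`, `saliencyOutline`,
#'   `styleCorrelation`, `consistency`.
#' @export
runVariants <- function(target, distractors, observer = NULL,
                        provider = NULL, layerId = NULL,
                        nVariants = 500L, angleJitterDeg = 20,
                        lengthJitter = 0.2, view = viewParams(),
                        augcfg = augmentationConfig(),
                        profile = experimentProfile("desk"),
                        nPerm = 100L, pTh = 0.01, seed = 1L) {
  geom <- augcfg@geom
  with_seed(seed, {
    classify <- if (!is.null(observer)) {
      function(images) {
        simulateResponses(observer, lapply(images, function(i)
          list(image = i)))
      }
    } else {
      if (is.null(provider) || is.null(layerId))
        stop("either an observer or provider + layerId is required")
      models <- c(list(target), distractors)
      tr <- render_condition_set(models, full_grid(view@sizeDeg),
                                 profile$nTrain, augcfg)
      lab2 <- ifelse(tr$labels == target@objectId, "target",
                     "distractor")
      ro <- readoutObserver(provider, tr$images, lab2, layerId)
      function(images) as.integer(ro$predict(images) == "target")
    }
    vr <- renderVariantSet(target, nVariants, view, geom, angleJitterDeg,
                           lengthJitter, seed = next_subseed())
    out_view <- viewParams(view@sizeDeg, view@azimuthDeg,
                           view@inplaneDeg, view@hshiftDeg, "outline")
    out_images <- lapply(vr$models, renderView, view = out_view,
                         geom = geom)
    reg_aug <- lapply(vr$images, augment, config = augcfg)
    out_aug <- lapply(out_images, augment, config = augcfg)
    ch_reg <- as.integer(classify(reg_aug))
    ch_out <- as.integer(classify(out_aug))
    sal_reg <- permutationSignificanceTripod(
      do.call(rbind, lapply(vr$images, as.numeric)), ch_reg, nPerm, pTh)
    sal_out <- permutationSignificanceTripod(
      do.call(rbind, lapply(out_images, as.numeric)), ch_out, nPerm, pTh)
    corr <- tryCatch(mapCorrelation(saliency(sal_reg), saliency(sal_out)),
                     error = function(e) NA_real_)
    new("ExperimentReport", experiment = "variants",
        artifacts = list(
          choiceRegular = ch_reg, choiceOutline = ch_out,
          fractionRegular = choiceFraction(ch_reg),
          fractionOutline = choiceFraction(ch_out),
          saliencyRegular = sal_reg, saliencyOutline = sal_out,
          styleCorrelation = corr,
          consistency = outlineConsistency(ch_reg, ch_out)),
        provenance = list(seed = seed, nVariants = nVariants,
                          angleJitterDeg = angleJitterDeg,
                          lengthJitter = lengthJitter))
  })
}
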