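#' Z-score normalization fitted on training activations
#'
#' Each unit is normalized to zero mean and unit variance (population SD)
#' across the training stimuli; the same statistics are then applied to
#' test activations. Units with zero training SD carry no information and
#' are dropped with a message.
#'
#' @param train stimulus x unit activation matrix.
#' @return list with `center`, `scale`, `keep` (retained unit indices).
#' @export
zscoreFit <- function(train) {
  mu <- colMeans(train)
  sdev <- sqrt(colMeans(sweep(train, 2, mu)^2))
  keep <- which(sdev > 0)
  if (length(keep) == 0) stop("all units are degenerate (zero variance)")
  if (length(keep) < length(sdev))
    message(sprintf("zscoreFit: dropped %d constant unit(s)",
                    length(sdev) - length(keep)))
  list(center = mu[keep], scale = sdev[keep], keep = keep)
}

#' @param stats a fit from [zscoreFit()].
#' @param x activation matrix to transform.
#' @rdname zscoreFit
#' @export
zscoreApply <- function(stats, x) {
  x <- x[, stats$keep, drop = FALSE]
  sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
}

#' Train a linear readout
#'
#' Linear SVM (margin-based, fixed regularization C = 1) predicting the
#' class label from an activation vector.
#'
#' @param activations stimulus x unit matrix (typically z-scored).
#' @param labels two-class factor/vector.
#' @param cost SVM regularization constant.
#' @return fitted classifier (class `svm`).
#' @export
trainReadout <- function(activations, labels, cost = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training labels contain a single class")
  e1071::svm(activations, labels, kernel = "linear", cost = cost,
             scale = FALSE)
}

#' Evaluate a readout per stimulus condition
#'
#' Fraction of correct predictions within every cell of the condition
#' design (cross of the unique values of each condition column).
#'
#' @param classifier fitted classifier from [trainReadout()].
#' @param activations test stimulus x unit matrix.
#' @param labels true labels.
#' @param conditions data.frame (one row per stimulus) whose columns index
#'   the condition axes, or a single vector.
#' @param metadata metadata list stored in the result.
#' @return an [AccuracyMatrix-class]; errors listing any empty cells.
#' @export
evaluateReadout <- function(classifier, activations, labels, conditions,
                            metadata = list()) {
  pred <- predict(classifier, activations)
  correct <- as.character(pred) == as.character(labels)
  if (!is.data.frame(conditions))
    conditions <- data.frame(condition = conditions)
  fs <- lapply(conditions, function(x) if (is.factor(x)) x else factor(x))
  acc <- tapply(correct, fs, mean)
  cnt <- tapply(correct, fs, length)
  if (any(is.na(cnt)) || any(cnt == 0)) {
    empty <- which(is.na(cnt) | cnt == 0, arr.ind = TRUE)
    stop("empty condition cell(s): ",
         paste(apply(as.matrix(empty), 1, paste, collapse = ","),
               collapse = "; "))
  }
  accuracyMatrix(acc, metadata)
}

check_matched <- function(reference, candidate) {
  a <- accuracy(reference)
  b <- accuracy(candidate)
  if (!identical(dim(a), dim(b)))
    stop("accuracy matrices have mismatched shapes")
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Compare accuracy patterns by L1 distance
#'
#' Mean absolute difference over matched condition cells (mean rather than
#' sum, so values are comparable across stimulus sets of different size).
#'
#' @param reference,candidate matched [AccuracyMatrix-class] objects.
#' @return non-negative scalar.
#' @export
compareL1 <- function(reference, candidate) {
  m <- check_matched(reference, candidate)
  mean(abs(m$a - m$b))
}

#' Compare accuracy patterns by Pearson correlation
#'
#' Scale- and shift-invariant similarity of the two accuracy patterns over
#' matched cells.
#'
#' @param reference,candidate matched [AccuracyMatrix-class] objects with
#'   at least 3 cells and non-constant values.
#' @return correlation in \[-1, 1\].
#' @export
comparePearson <- function(reference, candidate) {
  m <- check_matched(reference, candidate)
  if (length(m$a) < 3) stop("need at least 3 cells")
  if (stats::sd(m$a) == 0 || stats::sd(m$b) == 0)
    stop("Pearson comparison undefined for a constant accuracy pattern")
  stats::cor(m$a, m$b)
}

#' Histogram of per-curve extremum layers
#'
#' For a set of per-layer metric curves (e.g. L1 distance across runs and
#' population scales), counts at which layer each curve attains its
#' extremum. Ties are broken toward the shallower layer.
#'
#' @param curves matrix with one curve per row and layers in columns (or a
#'   list of equal-length numeric vectors).
#' @param mode `"min"` or `"max"`.
#' @return integer vector of counts, one per layer, summing to the number
#'   of curves.
#' @export
extremaHistogram <- function(curves, mode = c("min", "max")) {
  mode <- match.arg(mode)
  if (is.list(curves)) curves <- do.call(rbind, curves)
  if (!is.matrix(curves)) curves <- matrix(curves, nrow = 1)
  pick <- if (mode == "min") which.min else which.max
  keep <- rowSums(!is.na(curves)) > 0
  idx <- apply(curves[keep, , drop = FALSE], 1, pick)
  tabulate(idx, nbins = ncol(curves))
}

#' Pixel-based readout baseline
#'
#' Same normalization + linear SVM protocol as the layer readouts, but
#' with raw flattened pixels as features.
#'
#' @param trainImages,testImages lists of image matrices.
#' @param trainLabels,testLabels class labels.
#' @param conditions condition design for the test set (see
#'   [evaluateReadout()]).
#' @param cost SVM regularization constant.
#' @return an [AccuracyMatrix-class].
#' @export
pixelBaseline <- function(trainImages, trainLabels, testImages,
                          testLabels, conditions, cost = 1) {
  tr <- do.call(rbind, lapply(trainImages, as.numeric))
  te <- do.call(rbind, lapply(testImages, as.numeric))
  zs <- zscoreFit(tr)
  fit <- trainReadout(zscoreApply(zs, tr), trainLabels, cost)
  evaluateReadout(fit, zscoreApply(zs, te), testLabels, conditions,
                  metadata = list(features = "pixels"))
}
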