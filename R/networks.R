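#' Architecture specification of the parameter-matched MLP
#'
#' Layer dimensionalities of the 16-stage fully connected control network,
#' matched in depth and total parameter count to the 16-weight-layer
#' convolutional reference: input 224x224 = 50176 (single channel), then
#' 2150, 2048 (x4), 1024 (x10), output 1000.
#'
#' @return list with `kind = "mlp_table1"` and `dims` (N0..N16).
#' @export
mlpTable1Spec <- function() {
  list(kind = "mlp_table1",
       dims = c(50176, 2150, rep(2048, 4), rep(1024, 10), 1000))
}

#' Build the parameter-matched MLP
#'
#' 16 affine stages with bias and ReLU between stages (none after the
#' last), dimensioned by [mlpTable1Spec()]. Weights and biases are drawn
#' from the standard fan-in uniform scheme U(-1/sqrt(fanin),
#' +1/sqrt(fanin)), seeded.
#'
#' @param seed integer initialization seed.
#' @return an [MLPNetwork-class].
#' @export
buildMLPTable1 <- function(seed = 1L) {
  dims <- mlpTable1Spec()$dims
  with_seed(seed, {
    weights <- vector("list", 16L)
    biases <- vector("list", 16L)
    for (l in 1:16) {
      fan_in <- dims[l]
      bound <- 1 / sqrt(fan_in)
      weights[[l]] <- matrix(runif(dims[l + 1] * dims[l], -bound, bound),
                             nrow = dims[l + 1])
      biases[[l]] <- runif(dims[l + 1], -bound, bound)
    }
    new("MLPNetwork", dims = dims, weights = weights, biases = biases,
        seed = as.integer(seed))
  })
}

#' Architecture specification of the 16-weight-layer convolutional network
#'
#' The standard VGG-16 layout: 13 3x3 stride-1 pad-1 convolutions with
#' channel widths 64,64 / 128,128 / 256,256,256 / 512,512,512 /
#' 512,512,512 and 2x2 max pooling after layers 2, 4, 7, 10 and 13,
#' followed by fully connected stages 4096, 4096 and 1000. Weight layers
#' are indexed 1..16 (conv1..conv13, fc14..fc16).
#'
#' @param inputSize spatial input resolution (must be divisible by 32).
#' @param channels input channels (3 by default; grayscale stimuli are
#'   replicated).
#' @return list with `kind = "vgg16"` and `layers`, a list of per-layer
#'   descriptors.
#' @export
vgg16LayerSpec <- function(inputSize = 224L, channels = 3L) {
  inputSize <- as.integer(inputSize)
  if (inputSize %% 32L != 0L) stop("inputSize must be divisible by 32")
  widths <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512,
              512)
  pool_after <- c(2, 4, 7, 10, 13)
  layers <- list()
  in_ch <- channels
  sz <- inputSize
  for (l in seq_along(widths)) {
    layers[[l]] <- list(type = "conv", id = l, inCh = in_ch,
                        outCh = widths[l], k = 3L, pad = 1L,
                        spatial = sz, poolAfter = l %in% pool_after)
    in_ch <- widths[l]
    if (l %in% pool_after) sz <- sz %/% 2L
  }
  fc_dims <- c(512L * sz * sz, 4096L, 4096L, 1000L)
  for (f in 1:3) {
    layers[[13 + f]] <- list(type = "fc", id = 13L + f,
                             inDim = fc_dims[f], outDim = fc_dims[f + 1])
  }
  list(kind = "vgg16", inputSize = inputSize, channels = channels,
       layers = layers)
}

#' Build an untrained convolutional network
#'
#' Instantiates the [vgg16LayerSpec()] architecture with random weights
#' (fan-in uniform scheme, seeded). Pretrained weights are not bundled:
#' requesting them raises an error suggesting untrained mode, which every
#' analysis in this package supports.
#'
#' @param inputSize spatial input resolution; smaller values give a
#'   cheaper probe network with the same layout (the fully connected
#'   input dimension shrinks accordingly).
#' @param channels input channels.
#' @param init `"untrained_default"`; `"pretrained"` and
#'   `"pretrained_blur"` are recognized but unavailable.
#' @param seed integer initialization seed.
#' @return a [ConvNetwork-class].
#' @export
buildVGG16 <- function(inputSize = 224L, channels = 3L,
                       init = "untrained_default", seed = 1L) {
  if (init != "untrained_default")
    stop("init '", init, "' weights are not bundled with this package; ",
         "use init = 'untrained_default'")
  spec <- vgg16LayerSpec(inputSize, channels)
  with_seed(seed, {
    weights <- vector("list", 16L)
    biases <- vector("list", 16L)
    for (l in 1:16) {
      ly <- spec$layers[[l]]
      if (ly$type == "conv") {
        fan_in <- ly$inCh * ly$k^2
        bound <- 1 / sqrt(fan_in)
        weights[[l]] <- matrix(runif(ly$outCh * fan_in, -bound, bound),
                               nrow = ly$outCh)
        biases[[l]] <- runif(ly$outCh, -bound, bound)
      } else {
        bound <- 1 / sqrt(ly$inDim)
        weights[[l]] <- matrix(runif(ly$outDim * ly$inDim, -bound, bound),
                               nrow = ly$outDim)
        biases[[l]] <- runif(ly$outDim, -bound, bound)
      }
    }
    new("ConvNetwork", layers = spec$layers, weights = weights,
        biases = biases, inputSize = spec$inputSize,
        channels = as.integer(channels), seed = as.integer(seed))
  })
}

count_params <- function(layers) {
  rows <- lapply(layers, function(ly) {
    if (ly$type == "conv") {
      raw <- ly$k^2 * ly$inCh * ly$outCh + ly$outCh
      label <- sprintf("conv%d", ly$id)
    } else if (ly$type == "fc") {
      raw <- ly$inDim * ly$outDim + ly$outDim
      label <- sprintf("fc%d", ly$id)
    } else { # affine stage of the MLP
      raw <- ly$inDim * ly$outDim + ly$outDim
      label <- sprintf("M(%d)", ly$id)
    }
    data.frame(layer = ly$id, label = label, raw = raw,
               millions = round(raw / 1e6))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, totalRaw = sum(tab$raw),
       totalM = round(sum(tab$raw) / 1e6),
       totalRoundedM = sum(tab$millions))
}

mlp_layers_from_dims <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(type = "affine", id = l, inDim = dims[l], outDim = dims[l + 1])
  })
}

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "MLPNetwork", function(network) {
  count_params(mlp_layers_from_dims(network@dims))
})

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "ConvNetwork", function(network) {
  count_params(network@layers)
})

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "list", function(network) {
  if (identical(network$kind, "mlp_table1"))
    count_params(mlp_layers_from_dims(network$dims))
  else if (identical(network$kind, "vgg16"))
    count_params(network$layers)
  else stop("unknown network spec")
})

#' Per-layer unit counts
#'
#' Number of units (flattened pre-nonlinearity responses) of each weight
#' layer.
#'
#' @param network an [MLPNetwork-class], [ConvNetwork-class] or spec list.
#' @return integer vector of length 16.
#' @export
layerUnitCounts <- function(network) {
  layers <- if (is(network, "ConvNetwork")) network@layers
    else if (is(network, "MLPNetwork")) mlp_layers_from_dims(network@dims)
    else if (identical(network$kind, "vgg16")) network$layers
    else mlp_layers_from_dims(network$dims)
  vapply(layers, function(ly) {
    if (ly$type == "conv") as.integer(ly$outCh * ly$spatial^2)
    else as.integer(ly$outDim)
  }, integer(1))
}

as_input_array <- function(img, channels) {
  x <- array(0, dim = c(channels, nrow(img), ncol(img)))
  for (c in seq_len(channels)) x[c, , ] <- img
  x
}

conv_forward_to <- function(network, layerId, img) {
  x <- as_input_array(img, network@channels)
  for (l in 1:16) {
    ly <- network@layers[[l]]
    if (ly$type == "conv") {
      d <- dim(x)
      cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], ly$k, ly$pad)
      pre <- network@weights[[l]] %*% cols + network@biases[[l]]
      if (l == layerId) return(as.numeric(pre))
      post <- pmax(pre, 0)
      x <- array(post, dim = c(ly$outCh, d[2], d[3]))
      if (ly$poolAfter) {
        pooled <- cpp_maxpool2(as.numeric(x), ly$outCh, d[2], d[3])
        x <- array(pooled, dim = c(ly$outCh, d[2] %/% 2L, d[3] %/% 2L))
      }
    } else {
      v <- as.numeric(x)
      pre <- as.numeric(network@weights[[l]] %*% v + network@biases[[l]])
      if (l == layerId) return(pre)
      x <- pmax(pre, 0)
    }
  }
  stop("layerId must be in 1..16")
}

#' @rdname extractActivations
#' @export
setMethod("extractActivations", "ConvNetwork",
  function(network, layerId, images) {
    layerId <- as.integer(layerId)
    if (layerId < 1L || layerId > 16L) stop("layerId must be in 1..16")
    if (is.matrix(images) && !is.list(images)) images <- list(images)
    rows <- lapply(images, function(img) {
      if (nrow(img) != network@inputSize || ncol(img) != network@inputSize)
        stop(sprintf("image must be %dx%d for this network instance",
                     network@inputSize, network@inputSize))
      conv_forward_to(network, layerId, img)
    })
    do.call(rbind, rows)
  })

#' @rdname extractActivations
#' @export
setMethod("extractActivations", "MLPNetwork",
  function(network, layerId, images) {
    layerId <- as.integer(layerId)
    if (layerId < 1L || layerId > 16L) stop("layerId must be in 1..16")
    if (is.list(images))
      images <- do.call(rbind, lapply(images, as.numeric))
    if (!is.matrix(images)) images <- matrix(images, nrow = 1)
    # a single image matrix (e.g. 224 x 224) is one flattened stimulus
    if (ncol(images) != network@dims[1] &&
        length(images) == network@dims[1])
      images <- matrix(as.numeric(images), nrow = 1)
    if (ncol(images) != network@dims[1])
      stop(sprintf("expected %d input features", network@dims[1]))
    a <- images
    for (l in 1:16) {
      pre <- a %*% t(network@weights[[l]])
      pre <- sweep(pre, 2, network@biases[[l]], "+")
      if (l == layerId) return(unname(pre))
      a <- pmax(pre, 0)
    }
    stop("unreachable")
  })

#' Sample a unit subpopulation from a layer
#'
#' Uniform sample without replacement, capped at the layer size: when the
#' layer holds fewer units than requested the whole population is taken.
#'
#' @param layerSize total units in the layer.
#' @param requested requested population size (> 0).
#' @param layerId layer index recorded in the result.
#' @param seed optional integer seed.
#' @return a [UnitSample-class].
#' @export
sampleUnits <- function(layerSize, requested, layerId = 1L, seed = NULL) {
  if (requested <= 0) stop("requested population size must be > 0")
  n <- min(as.integer(requested), as.integer(layerSize))
  idx <- with_seed(seed, {
    if (n == layerSize) seq_len(layerSize) else sample.int(layerSize, n)
  })
  new("UnitSample", layerId = as.integer(layerId),
      indices = as.integer(idx), requested = as.integer(requested))
}

#' Synthetic depth-indexed activations
#'
#' A toy stand-in for a deep network in which layer k encodes object
#' identity linearly with signal-to-noise ratio increasing in k: unit u of
#' layer k responds `snr_k * (1 - difficulty_i) * y_i * beta_u + noise`
#' for stimulus i with label `y_i` in \{-1, +1\} and a per-condition
#' difficulty in \[0, 1\]. Useful for validating depth-trend analyses at
#' desk scale.
#'
#' @param labels integer/numeric vector of class labels (coerced to
#'   -1/+1).
#' @param difficulty per-stimulus difficulty in \[0, 1\].
#' @param nLayers number of layers.
#' @param nUnits units per layer.
#' @param snrRange range of the per-layer SNR, interpolated
#'   logarithmically across layers.
#' @param seed optional integer seed.
#' @return list of stimulus x unit activation matrices, one per layer.
#' @export
simulateLadderActivations <- function(labels, difficulty, nLayers = 6L,
                                      nUnits = 50L,
                                      snrRange = c(0.05, 1.5),
                                      seed = NULL) {
  y <- ifelse(labels == labels[1], 1, -1)
  if (length(unique(labels)) != 2) stop("need exactly two classes")
  snr <- exp(seq(log(snrRange[1]), log(snrRange[2]),
                 length.out = nLayers))
  with_seed(seed, {
    lapply(seq_len(nLayers), function(k) {
      beta <- rnorm(nUnits)
      signal <- outer(snr[k] * (1 - difficulty) * y, beta)
      signal + matrix(rnorm(length(signal)), nrow = nrow(signal))
    })
  })
}
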