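#' @include nn.R AllGenerics.R
NULL

#' Multi-task network architecture configuration
#'
#' The network is fully convolutional: a shared encoder of three
#' downsampling blocks (each a stride-1 3x3x3 convolution followed by a
#' stride-2 one, channels 16/32/64), a bottleneck convolution to 128
#' channels, and two parallel decoders with mirrored upsampling blocks
#' (stride-2 3x3x3 deconvolution then stride-1 convolution, channels
#' 64/32/16) ending in a 1x1x1 convolution to one channel. Batch
#' normalization and ReLU follow every (de)convolution except the final
#' 1x1x1 layer, after which an optional nonnegativity clamp is applied
#' (activities are nonnegative).
#'
#' @param encChannels encoder block channels; must have length 3.
#' @param bottleneck bottleneck channels.
#' @param decChannels decoder block channels; must have length 3.
#' @param anglePolicy how the sinogram angle axis (e.g. 160 columns) is
#'   matched to the image width (e.g. 128): \code{"resample"} linearly
#'   resamples the angle axis to the image width before the encoder
#'   (default); \code{"crop"} keeps the angle axis through the network and
#'   centrally crops the decoder output to the image width.
#' @param finalClamp clamp network outputs at 0 at inference (default
#'   TRUE; activities are nonnegative). Training always operates on the
#'   raw final-layer outputs: clamping inside the training graph acts as
#'   a mostly-dead output ReLU and stalls optimization.
#' @return a validated configuration list of class "networkConfig".
#' @examples
#' networkConfig()
#' @export
networkConfig <- function(encChannels = c(16L, 32L, 64L), bottleneck = 128L,
                          decChannels = c(64L, 32L, 16L),
                          anglePolicy = c("resample", "crop"),
                          finalClamp = TRUE) {
  anglePolicy <- match.arg(anglePolicy)
  if (length(encChannels) != 3L || length(decChannels) != 3L)
    stop("encChannels and decChannels must each have length 3")
  if (any(c(encChannels, bottleneck, decChannels) < 1))
    stop("channel counts must be positive")
  structure(list(encChannels = as.integer(encChannels),
                 bottleneck = as.integer(bottleneck),
                 decChannels = as.integer(decChannels),
                 anglePolicy = anglePolicy,
                 finalClamp = isTRUE(finalClamp)),
            class = "networkConfig")
}

makeEncoder <- function(cfg) {
  ch <- cfg$encChannels
  list(convLayer(1L, ch[1], stride = 1L), bnLayer(ch[1]), reluLayer(),
       convLayer(ch[1], ch[1], stride = 2L), bnLayer(ch[1]), reluLayer(),
       convLayer(ch[1], ch[2], stride = 1L), bnLayer(ch[2]), reluLayer(),
       convLayer(ch[2], ch[2], stride = 2L), bnLayer(ch[2]), reluLayer(),
       convLayer(ch[2], ch[3], stride = 1L), bnLayer(ch[3]), reluLayer(),
       convLayer(ch[3], ch[3], stride = 2L), bnLayer(ch[3]), reluLayer(),
       convLayer(ch[3], cfg$bottleneck, stride = 1L),
       bnLayer(cfg$bottleneck), reluLayer())
}

makeDecoder <- function(cfg) {
  dc <- cfg$decChannels
  list(tconvLayer(cfg$bottleneck, dc[1]), bnLayer(dc[1]), reluLayer(),
       convLayer(dc[1], dc[1], stride = 1L), bnLayer(dc[1]), reluLayer(),
       tconvLayer(dc[1], dc[2]), bnLayer(dc[2]), reluLayer(),
       convLayer(dc[2], dc[2], stride = 1L), bnLayer(dc[2]), reluLayer(),
       tconvLayer(dc[2], dc[3]), bnLayer(dc[3]), reluLayer(),
       convLayer(dc[3], dc[3], stride = 1L), bnLayer(dc[3]), reluLayer(),
       convLayer(dc[3], 1L, k = 1L, stride = 1L, pad = 0L))
}

#' Build the multi-task reconstruction network
#'
#' One shared encoder over the dual-tracer dynamic sinogram and two
#' structurally identical decoders with independent weights, one per
#' tracer. Weight initialization is a fan-in scheme seeded by
#' \code{seed}, so construction is deterministic. The network is fully
#' convolutional: its parameter count does not depend on the input frame
#' count or spatial size.
#'
#' @param config a [networkConfig()] list.
#' @param seed RNG seed for weight initialization.
#' @return a [ReconModel-class].
#' @examples
#' model <- buildNetwork(networkConfig(), seed = 1)
#' parameterCount(model)
#' @export
buildNetwork <- function(config = networkConfig(), seed = 0L) {
  net <- withSeed(seed, list(encoder = makeEncoder(config),
                             dec1 = makeDecoder(config),
                             dec2 = makeDecoder(config)))
  new("ReconModel", net = net, config = unclass(config),
      meta = list(seed = seed, norm = NULL, log = NULL))
}

# interpolation matrix taking `from` columns to `to` columns (linear)
angleResampleMatrix <- function(from, to) {
  pos <- seq(1, from, length.out = to)
  lo <- pmin(floor(pos), from - 1L)
  fr <- pos - lo
  M <- matrix(0, from, to)
  for (j in seq_len(to)) {
    M[lo[j], j] <- 1 - fr[j]
    M[lo[j] + 1L, j] <- fr[j]
  }
  M
}

# sinogram array (bins x angles x F) -> network input tensor (W,H,D,1,1)
sinoToTensor <- function(sinoData, targetW, anglePolicy) {
  d <- dim(sinoData)
  if (anglePolicy == "resample" && d[2] != targetW) {
    M <- angleResampleMatrix(d[2], targetW)
    res <- array(0, dim = c(d[1], targetW, d[3]))
    for (f in seq_len(d[3])) res[, , f] <- sinoData[, , f] %*% M
    sinoData <- res
    d <- dim(sinoData)
  }
  t5 <- aperm(sinoData, c(2, 1, 3))           # (Wlike, bins, F)
  tensor5(t5, d[2], d[1], d[3])
}

# network output tensor (W,H,D,1,N) -> list of H x W x F arrays
tensorToImages <- function(y, targetW = NULL) {
  d <- dim(y)
  out <- vector("list", d[5])
  for (n in seq_len(d[5])) {
    arr <- array(y[, , , 1, n], d[1:3])
    if (!is.null(targetW) && d[1] != targetW) {   # central crop (angle axis)
      off <- (d[1] - targetW) %/% 2
      arr <- arr[(off + 1):(off + targetW), , , drop = FALSE]
    }
    out[[n]] <- aperm(arr, c(2, 1, 3))
  }
  out
}

# Full forward pass on a batch tensor; returns outputs and caches needed
# for the backward pass.
netForward <- function(net, x, train = TRUE) {
  dIn <- dim(x)[1:3]
  if (any(dIn < 4L))
    stop("every input axis needs size >= 4 (three stride-2 halvings)")
  enc <- stackForward(net$encoder, x, train = train)
  targets <- rev(enc$sizes)
  d1 <- stackForward(net$dec1, enc$y, train = train, targetSizes = targets)
  d2 <- stackForward(net$dec2, enc$y, train = train, targetSizes = targets)
  list(y1 = d1$y, y2 = d2$y,
       cache = list(enc = enc, d1 = d1, d2 = d2),
       net = list(encoder = enc$layers, dec1 = d1$layers, dec2 = d2$layers))
}

netBackward <- function(net, cache, dy1, dy2) {
  b1 <- stackBackward(net$dec1, cache$d1$caches, dy1)
  b2 <- stackBackward(net$dec2, cache$d2$caches, dy2)
  be <- stackBackward(net$encoder, cache$enc$caches, b1$dx + b2$dx)
  list(grads = list(encoder = be$grads, dec1 = b1$grads, dec2 = b2$grads))
}

#' Reconstruct both single-tracer image sequences from a dual-tracer
#' sinogram
#'
#' Runs the trained model in inference mode (batch-norm running
#' statistics, no caching). If the model carries normalization metadata
#' (from [trainModel()]), the input is standardized with the stored
#' training-set mean/sd and the outputs are rescaled from the label scale
#' back to activity units; otherwise the raw network outputs are
#' returned.
#'
#' @param model a [ReconModel-class].
#' @param dualSino a [DynamicSinogram-class] (dual-tracer input).
#' @return list with two [DynamicImage-class] objects \code{I} and
#'   \code{II}.
#' @export
reconForward <- function(model, dualSino) {
  g <- dualSino@geometry
  cfg <- model@config
  targetW <- g@imageSize[2]
  x <- sinoToTensor(dualSino@data, targetW, cfg$anglePolicy)
  norm <- model@meta$norm
  if (!is.null(norm)) x <- (x - norm$mean) / norm$sd
  fw <- netForward(model@net, x, train = FALSE)
  cropW <- if (cfg$anglePolicy == "crop") targetW else NULL
  imgs <- lapply(list(fw$y1, fw$y2), function(y) {
    arr <- tensorToImages(y, cropW)[[1]]
    if (cfg$finalClamp) arr <- pmax(arr, 0)
    if (!is.null(norm)) arr <- arr * norm$labelScale
    arr
  })
  list(I = new("DynamicImage", data = pmax(imgs[[1]], 0),
               protocol = dualSino@protocol, tracer = "tracerI"),
       II = new("DynamicImage", data = pmax(imgs[[2]], 0),
                protocol = dualSino@protocol, tracer = "tracerII"))
}

#' Total number of trainable parameters
#' @param model a [ReconModel-class].
#' @return integer parameter count over encoder and both decoders.
#' @export
parameterCount <- function(model) {
  cnt <- function(stack) sum(vapply(stack, function(ly) {
    sum(vapply(paramNamesOf(ly), function(p) length(ly[[p]]), numeric(1)), 0)
  }, numeric(1)))
  sum(vapply(model@net, cnt, numeric(1)))
}

#' Layer table of a reconstruction model
#' @param model a [ReconModel-class].
#' @return data.frame with one row per layer: stack, index, type,
#'   channels, stride and parameter count.
#' @export
describeModel <- function(model) {
  rows <- list()
  for (sn in names(model@net)) {
    for (i in seq_along(model@net[[sn]])) {
      ly <- model@net[[sn]][[i]]
      np <- sum(vapply(paramNamesOf(ly),
                       function(p) length(ly[[p]]), numeric(1)), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        stack = sn, index = i, type = ly$type,
        in_ch = if (!is.null(ly$inCh)) ly$inCh else NA,
        out_ch = if (!is.null(ly$outCh)) ly$outCh
                 else if (!is.null(ly$ch)) ly$ch else NA,
        stride = if (!is.null(ly$stride)) ly$stride else NA,
        n_params = np)
    }
  }
  do.call(rbind, rows)
}

setMethod("show", "ReconModel", function(object) {
  cat(sprintf("ReconModel: multi-task CNN, %d parameters (%s angle policy)\n",
              parameterCount(object), object@config$anglePolicy))
  tab <- describeModel(object)
  agg <- tapply(tab$n_params, tab$stack, sum)
  for (sn in names(agg))
    cat(sprintf("  %-8s %2d layers, %8d params\n", sn,
                sum(tab$stack == sn), agg[[sn]]))
  if (!is.null(object@meta$norm))
    cat(sprintf("  trained: input mean %.4g sd %.4g, label scale %g\n",
                object@meta$norm$mean, object@meta$norm$sd,
                object@meta$norm$labelScale))
})
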