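# Minimal 3D convolutional network machinery used by the multi-task
# reconstruction model: conv / transposed-conv / batch-norm / ReLU layers
# with explicit forward and backward passes (C++ im2col kernels underneath)
# and an Adam optimizer. Tensors are 5-D arrays dim = c(W, H, D, C, N).

tensor5 <- function(x, W, H, D, C = 1L, N = 1L) {
  x <- as.numeric(x)
  dim(x) <- c(W, H, D, C, N)
  x
}

# per-channel sums of a 5-D tensor -> numeric length C
channelSums <- function(x) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4] * d[5])
  cs <- colSums(m)
  rowSums(matrix(cs, d[4], d[5]))
}

# multiply/add a per-channel vector into a 5-D tensor
chanOp <- function(x, g, op = c("*", "+")) {
  op <- match.arg(op)
  d <- dim(x)
  gcol <- rep(rep(g, d[5]), each = prod(d[1:3]))
  y <- if (op == "*") as.numeric(x) * gcol else as.numeric(x) + gcol
  dim(y) <- d
  y
}

## ---- layer constructors -------------------------------------------------

convLayer <- function(inCh, outCh, k = 3L, stride = 1L, pad = 1L) {
  K <- inCh * k^3
  sd <- sqrt(2 / K)  # He fan-in initialization
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), inCh = inCh, outCh = outCh,
       w = matrix(stats::rnorm(outCh * K, 0, sd), outCh, K),
       b = numeric(outCh))
}

tconvLayer <- function(inCh, outCh, k = 3L, stride = 2L, pad = 1L) {
  # stored as the weights of the adjoint convolution outCh -> inCh
  K <- outCh * k^3
  sd <- sqrt(2 / (inCh * k^3))
  list(type = "tconv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), inCh = inCh, outCh = outCh,
       w = matrix(stats::rnorm(inCh * K, 0, sd), inCh, K),
       b = numeric(outCh))
}

bnLayer <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", ch = ch, eps = eps, momentum = momentum,
       gamma = rep(1, ch), beta = numeric(ch),
       runMean = numeric(ch), runVar = rep(1, ch))
}

reluLayer <- function() list(type = "relu")

## ---- forward / backward -------------------------------------------------

# Returns list(y, cache, layer). `outSize` is required for tconv layers
# (the exact target spatial size recorded by the encoder).
layerForward <- function(layer, x, train = TRUE, outSize = NULL) {
  switch(layer$type,
    conv = {
      y <- cpp_conv3d_fwd(x, layer$w, layer$b, layer$k, layer$stride,
                          layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    tconv = {
      if (is.null(outSize)) stop("tconv layer needs a target output size")
      d <- dim(x)
      y <- cpp_conv3d_bwd_data(x, layer$w, layer$k, layer$stride, layer$pad,
                               as.integer(outSize))
      y <- chanOp(y, layer$b, "+")
      list(y = y, cache = list(x = x, outSize = outSize), layer = layer)
    },
    bn = {
      d <- dim(x)
      nc <- prod(d[1:3]) * d[5]
      m <- channelSums(x) / nc
      xc <- chanOp(x, -m, "+")
      v <- channelSums(xc * xc) / nc
      if (train) {
        layer$runMean <- (1 - layer$momentum) * layer$runMean +
          layer$momentum * m
        layer$runVar <- (1 - layer$momentum) * layer$runVar +
          layer$momentum * v
        useM <- m; useV <- v
      } else {
        useM <- layer$runMean; useV <- layer$runVar
        xc <- chanOp(x, -useM, "+")
      }
      invstd <- 1 / sqrt(useV + layer$eps)
      xhat <- chanOp(xc, invstd, "*")
      y <- chanOp(chanOp(xhat, layer$gamma, "*"), layer$beta, "+")
      list(y = y, cache = list(xhat = xhat, invstd = invstd, nc = nc),
           layer = layer)
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask), layer = layer)
    },
    stop("unknown layer type"))
}

# Returns list(dx, grads); grads is NULL for parameter-free layers.
layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      d <- dim(cache$x)
      dx <- cpp_conv3d_bwd_data(dy, layer$w, layer$k, layer$stride,
                                layer$pad, d[1:3])
      dw <- cpp_conv3d_bwd_filter(cache$x, dy, layer$k, layer$stride,
                                  layer$pad)
      list(dx = dx, grads = list(w = dw, b = channelSums(dy)))
    },
    tconv = {
      dx <- cpp_conv3d_fwd(dy, layer$w, numeric(layer$inCh), layer$k,
                           layer$stride, layer$pad)
      dw <- cpp_conv3d_bwd_filter(dy, cache$x, layer$k, layer$stride,
                                  layer$pad)
      list(dx = dx, grads = list(w = dw, b = channelSums(dy)))
    },
    bn = {
      xhat <- cache$xhat
      dxhat <- chanOp(dy, layer$gamma, "*")
      md <- channelSums(dxhat) / cache$nc
      mdx <- channelSums(dxhat * xhat) / cache$nc
      dx <- chanOp(dxhat - chanOp(xhat, mdx, "*"), -md, "+")
      dx <- chanOp(dx, cache$invstd, "*")
      list(dx = dx, grads = list(gamma = channelSums(dy * xhat),
                                 beta = channelSums(dy)))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    stop("unknown layer type"))
}

# Run a stack of layers. For encoders, record the input spatial size of
# every strided conv; for decoders, feed those sizes (reversed) to the
# tconv layers.
stackForward <- function(layers, x, train = TRUE, targetSizes = NULL) {
  caches <- vector("list", length(layers))
  sizes <- list()
  ti <- 0L
  updated <- layers
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    outSize <- NULL
    if (ly$type == "conv" && ly$stride > 1L)
      sizes[[length(sizes) + 1L]] <- dim(x)[1:3]
    if (ly$type == "tconv") {
      ti <- ti + 1L
      outSize <- targetSizes[[ti]]
    }
    fw <- layerForward(ly, x, train = train, outSize = outSize)
    x <- fw$y
    caches[[i]] <- fw$cache
    updated[[i]] <- fw$layer
  }
  list(y = x, caches = caches, layers = updated, sizes = sizes)
}

stackBackward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layerBackward(layers[[i]], caches[[i]], dy)
    dy <- bw$dx
    grads[i] <- list(bw$grads)  # keep NULL entries in place
  }
  list(dx = dy, grads = grads)
}

## ---- Adam ----------------------------------------------------------------

paramNamesOf <- function(layer)
  switch(layer$type, conv = , tconv = c("w", "b"),
         bn = c("gamma", "beta"), character(0))

adamInit <- function(net) {
  lapply(net, function(stack) lapply(stack, function(ly) {
    pn <- paramNamesOf(ly)
    if (length(pn) == 0) return(NULL)
    st <- lapply(pn, function(p) list(m = ly[[p]] * 0, v = ly[[p]] * 0))
    stats::setNames(st, pn)
  }))
}

adamStep <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  for (sn in names(net)) {
    for (i in seq_along(net[[sn]])) {
      g <- grads[[sn]][[i]]
      if (is.null(g)) next
      for (p in names(g)) {
        gr <- g[[p]]
        if (weightDecay > 0 && p == "w")
          gr <- gr + weightDecay * net[[sn]][[i]][[p]]
        st <- state[[sn]][[i]][[p]]
        st$m <- beta1 * st$m + (1 - beta1) * gr
        st$v <- beta2 * st$v + (1 - beta2) * gr^2
        mh <- st$m / (1 - beta1^t)
        vh <- st$v / (1 - beta2^t)
        net[[sn]][[i]][[p]] <- net[[sn]][[i]][[p]] - lr * mh / (sqrt(vh) + eps)
        state[[sn]][[i]][[p]] <- st
      }
    }
  }
  list(net = net, state = state)
}
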