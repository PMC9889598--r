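test_that("the two decoder branches are structurally identical twins", {
  model <- buildNetwork(networkConfig(), seed = 1)
  tab <- describeModel(model)
  expect_equal(sum(tab$n_params[tab$stack == "dec1"]),
               sum(tab$n_params[tab$stack == "dec2"]))
  # encoder channel progression ends at the bottleneck width
  enc <- tab[tab$stack == "encoder" & tab$type == "conv", ]
  expect_equal(enc$out_ch, c(16, 16, 32, 32, 64, 64, 128))

  # deterministic initialization per seed
  m2 <- buildNetwork(networkConfig(), seed = 1)
  expect_identical(model@net$encoder[[1]]$w, m2@net$encoder[[1]]$w)
  m3 <- buildNetwork(networkConfig(), seed = 2)
  expect_false(identical(model@net$encoder[[1]]$w, m3@net$encoder[[1]]$w))
})

test_that("the network is fully convolutional across input sizes", {
  model <- buildNetwork(networkConfig(), seed = 1)
  nPar <- parameterCount(model)

  prot6 <- deskProtocol()
  sino <- new("DynamicSinogram",
              data = array(abs(sin(seq_len(32 * 40 * 6))), c(32, 40, 6)),
              geometry = deskGeometry(32, 40), protocol = prot6)
  out <- reconForward(model, sino)
  expect_equal(dim(dataArray(out$I)), c(32L, 32L, 6L))
  expect_equal(dim(dataArray(out$II)), c(32L, 32L, 6L))

  # same weights applied to a full-scale input: 18 x 128 bins x 160
  # angles in, two 18-frame 128 x 128 sequences out
  protP <- parseProtocol("30s×4+110s×12+180s×2")
  sinoP <- new("DynamicSinogram",
               data = array(abs(cos(seq_len(128 * 160 * 18) / 999)),
                            c(128, 160, 18)),
               geometry = systemGeometry(), protocol = protP)
  outP <- reconForward(model, sinoP)
  expect_equal(dim(dataArray(outP$I)), c(128L, 128L, 18L))
  expect_equal(parameterCount(model), nPar)

  # frame counts below 4 cannot survive three stride-2 halvings
  protS <- scanProtocol(rep(60, 3))
  sinoS <- new("DynamicSinogram", data = array(1, c(32, 40, 3)),
               geometry = deskGeometry(32, 40), protocol = protS)
  expect_error(reconForward(model, sinoS), ">= 4")
})

test_that("inference is deterministic and the encoder is shared", {
  model <- buildNetwork(networkConfig(), seed = 4)
  sino <- new("DynamicSinogram",
              data = array(abs(sin(seq_len(32 * 40 * 6))), c(32, 40, 6)),
              geometry = deskGeometry(32, 40), protocol = deskProtocol())
  o1 <- reconForward(model, sino)
  o2 <- reconForward(model, sino)
  expect_identical(dataArray(o1$I), dataArray(o2$I))
  expect_identical(dataArray(o1$II), dataArray(o2$II))

  # perturbing decoder I changes output I only
  mI <- model
  mI@net$dec1[[4]]$w <- mI@net$dec1[[4]]$w + 0.05
  oI <- reconForward(mI, sino)
  expect_false(identical(dataArray(oI$I), dataArray(o1$I)))
  expect_identical(dataArray(oI$II), dataArray(o1$II))

  # perturbing the shared encoder changes both outputs
  mE <- model
  mE@net$encoder[[1]]$w <- mE@net$encoder[[1]]$w + 0.05
  oE <- reconForward(mE, sino)
  expect_false(identical(dataArray(oE$I), dataArray(o1$I)))
  expect_false(identical(dataArray(oE$II), dataArray(o1$II)))
})

test_that("the decode-then-crop angle policy also restores image width", {
  model <- buildNetwork(networkConfig(anglePolicy = "crop"), seed = 2)
  sino <- new("DynamicSinogram",
              data = array(1 + sin(seq_len(32 * 40 * 6)) / 2, c(32, 40, 6)),
              geometry = deskGeometry(32, 40), protocol = deskProtocol())
  out <- reconForward(model, sino)
  expect_equal(dim(dataArray(out$I)), c(32L, 32L, 6L))
})

test_that("network layer gradients agree with finite differences", {
  dt <- asNamespace("dualtracer")
  set.seed(41)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))
  eps <- 1e-6

  checkLayer <- function(ly, outSize = NULL) {
    fw <- dt$layerForward(ly, x, train = TRUE, outSize = outSize)
    co <- array(rnorm(length(fw$y)), dim(fw$y))
    bw <- dt$layerBackward(ly, fw$cache, co)
    for (i in c(3, 57, 120)) {
      xp <- x; xp[i] <- xp[i] + eps
      fd <- (sum(dt$layerForward(ly, xp, train = TRUE,
                                 outSize = outSize)$y * co) -
               sum(fw$y * co)) / eps
      expect_equal(bw$dx[i], fd, tolerance = 1e-4)
    }
    if (!is.null(bw$grads$w)) {
      lp <- ly; j <- 5; lp$w[j] <- lp$w[j] + eps
      fd <- (sum(dt$layerForward(lp, x, train = TRUE,
                                 outSize = outSize)$y * co) -
               sum(fw$y * co)) / eps
      expect_equal(bw$grads$w[j], fd, tolerance = 1e-4)
    }
  }
  checkLayer(dt$convLayer(2L, 3L, stride = 1L))
  checkLayer(dt$convLayer(2L, 3L, stride = 2L))
  checkLayer(dt$tconvLayer(2L, 3L), outSize = c(8L, 8L, 8L))
  bn <- dt$bnLayer(2L); bn$gamma <- c(0.7, 1.3); bn$beta <- c(0.1, -0.2)
  checkLayer(bn)
})
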