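#' @include network.R loss.R metrics.R osem.R io.R kinetics.R phantom.R
NULL

#' Experiment configuration
#'
#' Bundles every knob of a dataset-build / training / evaluation run.
#' The full-scale simulation profile is 40 phantoms x 30 parameter sets
#' (1200 groups) of 128 x 128 images and 128 x 160 sinograms with an
#' 18-frame protocol, trained for 100 epochs; [deskConfig()] provides a
#' CPU-friendly profile with the same structure.
#'
#' @param tracers character pair of built-in tracer names, or a list of
#'   two [TracerSpec-class] objects.
#' @param protocol protocol string (see [parseProtocol()]).
#' @param kineticCV,inputCV coefficients of variation of the Gaussian
#'   parameter randomization (the study "variation" percentages; default
#'   0.10 each).
#' @param nParameterSets randomized parameter sets per phantom.
#' @param nPhantoms number of phantoms.
#' @param imageSize image side length in pixels.
#' @param nBins,nAngles sinogram geometry.
#' @param countLevel expected counts per frame before noise.
#' @param randomsFraction randoms fraction of total counts (default 0.2).
#' @param osemIter,osemSubsets OSEM settings for label reconstruction
#'   (defaults 6 and 5).
#' @param split train/validation/test ratios, must sum to 1 (default
#'   8:1:1).
#' @param lr,epochs,batchSize Adam settings (simulation defaults 5e-4,
#'   100, 4).
#' @param alpha,beta loss weights (simulation defaults 100, 1).
#' @param weightDecay L2 coefficient added to the loss (default 0).
#' @param labelScale labels are divided by this constant (simulation
#'   convention 255).
#' @param decay apply physical decay in the simulator (default TRUE).
#' @param seed master seed; every stage derives child seeds from it.
#' @param outDir dataset directory (default: fresh tempdir subdirectory).
#' @param netConfig a [networkConfig()].
#' @return a list of class "experimentConfig".
#' @export
experimentConfig <- function(tracers = c("FMZ", "Acetate"),
                             protocol = "30s×4+110s×12+180s×2",
                             kineticCV = 0.10, inputCV = 0.10,
                             nParameterSets = 30L, nPhantoms = 40L,
                             imageSize = 128L, nBins = 128L, nAngles = 160L,
                             countLevel = 5e5, randomsFraction = 0.2,
                             osemIter = 6L, osemSubsets = 5L,
                             split = c(train = 0.8, val = 0.1, test = 0.1),
                             lr = 5e-4, epochs = 100L, batchSize = 4L,
                             alpha = 100, beta = 1, weightDecay = 0,
                             labelScale = 255, decay = TRUE, seed = 0L,
                             outDir = NULL, netConfig = networkConfig()) {
  if (is.character(tracers)) {
    if (length(tracers) != 2L) stop("exactly two tracers are required")
    tracers <- lapply(tracers, defaultTracer)
  }
  if (length(tracers) != 2L || !all(vapply(tracers, is, logical(1),
                                           "TracerSpec")))
    stop("'tracers' must name or contain exactly two TracerSpec objects")
  if (abs(sum(split) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (any(c(nParameterSets, nPhantoms, epochs, batchSize) < 1))
    stop("all counts must be >= 1")
  structure(list(tracers = tracers, protocol = protocol,
                 kineticCV = kineticCV, inputCV = inputCV,
                 nParameterSets = as.integer(nParameterSets),
                 nPhantoms = as.integer(nPhantoms),
                 imageSize = as.integer(imageSize),
                 nBins = as.integer(nBins), nAngles = as.integer(nAngles),
                 countLevel = countLevel,
                 randomsFraction = randomsFraction,
                 osemIter = as.integer(osemIter),
                 osemSubsets = as.integer(osemSubsets), split = split,
                 lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), alpha = alpha,
                 beta = beta, weightDecay = weightDecay,
                 labelScale = labelScale, decay = decay,
                 seed = as.integer(seed), outDir = outDir,
                 netConfig = netConfig),
            class = "experimentConfig")
}

#' Desk-scale experiment profile
#'
#' A small end-to-end profile that exercises the full pipeline on a
#' single CPU: 32 x 32 phantoms, 32 bins x 40 angles, a 6-frame 30-minute
#' protocol (the frame count compressed, the scan duration kept at the
#' full dual C-11 study length so the tracers' kinetic divergence is
#' preserved), 4 phantoms x 5 parameter sets = 20 groups and 20 epochs.
#' Training uses batch size 1 (16 gradient steps per epoch), learning
#' rate 1e-3 and a label-scale constant matched to the desk intensity
#' range; see the methods vignette for the calibration rationale.
#' Intended for tests and smoke runs; the full-scale profile is
#' [experimentConfig()]'s defaults.
#'
#' @param ... overrides passed to [experimentConfig()].
#' @return a list of class "experimentConfig".
#' @export
deskConfig <- function(...) {
  args <- list(protocol = "120s×2+300s×2+480s×2",
               nParameterSets = 5L, nPhantoms = 4L, imageSize = 32L,
               nBins = 32L, nAngles = 40L, countLevel = 2e5,
               epochs = 20L, seed = 0L, lr = 1e-3, batchSize = 1L,
               labelScale = 64)
  override <- list(...)
  args[names(override)] <- override
  do.call(experimentConfig, args)
}

#' Animal-study configuration preset
#'
#' The alternative hyperparameter arm used for real scanner data: labels
#' scaled by 1e6 (Bq/mL to MBq/mL), loss weights alpha = 1, beta = 0.01,
#' learning rate 1e-4 and weight decay 0.01. No real-data loader is
#' provided; this preset exists so the hyperparameters live in one place.
#'
#' @param ... overrides passed to [experimentConfig()].
#' @return a list of class "experimentConfig".
#' @export
animalConfig <- function(...) {
  args <- list(labelScale = 1e6, alpha = 1, beta = 0.01, lr = 1e-4,
               weightDecay = 0.01)
  override <- list(...)
  args[names(override)] <- override
  do.call(experimentConfig, args)
}

splitAssign <- function(n, split, seed) {
  nTest <- round(split[["test"]] * n)
  nVal <- round(split[["val"]] * n)
  if (nTest + nVal >= n) stop("split leaves no training samples")
  withSeed(seed, {
    ord <- sample.int(n)
    out <- rep("train", n)
    out[ord[seq_len(nTest)]] <- "test"
    out[ord[nTest + seq_len(nVal)]] <- "val"
    out
  })
}

#' Build (or plan) a simulated dual-tracer dataset
#'
#' For every (phantom, parameter set) group: simulate both tracers'
#' noise-free dynamic images from the compartment model, forward project,
#' add Poisson + randoms noise per tracer, sum the two noisy sinograms
#' into the dual-tracer network input, and OSEM-reconstruct each noisy
#' single-tracer sinogram into the training labels. Groups are assigned
#' to train/validation/test partitions at the group level (test and
#' validation sizes are \code{round(ratio * N)}; training takes the
#' remainder). Fully deterministic for a fixed config seed.
#'
#' @param config an [experimentConfig()].
#' @param simulate if FALSE, only the manifest (group table, partition
#'   assignment, file paths) is constructed and no data are written;
#'   useful for combinatorics checks at full scale.
#' @param verbose print progress.
#' @return a data.frame manifest (one row per group: ids, partition,
#'   file paths) with the config, phantom library and geometry attached
#'   as attributes.
#' @export
buildDataset <- function(config, simulate = TRUE, verbose = FALSE) {
  nGroups <- config$nPhantoms * config$nParameterSets
  prot <- parseProtocol(config$protocol)
  manifest <- expand.grid(paramSet = seq_len(config$nParameterSets),
                          phantom = seq_len(config$nPhantoms))
  manifest <- manifest[, c("phantom", "paramSet")]
  manifest$group <- seq_len(nGroups)
  manifest$partition <- splitAssign(nGroups, config$split,
                                    childSeed(config$seed, "split"))
  outDir <- config$outDir
  if (is.null(outDir))
    outDir <- file.path(tempdir(), sprintf("dualtracer_ds_%d", config$seed))
  manifest$dual <- file.path(outDir, sprintf("g%04d_dual.nii", manifest$group))
  manifest$labelI <- file.path(outDir, sprintf("g%04d_labI.nii", manifest$group))
  manifest$labelII <- file.path(outDir, sprintf("g%04d_labII.nii", manifest$group))

  attr(manifest, "config") <- config
  attr(manifest, "protocol") <- prot
  if (!simulate) return(manifest)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  phantoms <- makePhantomLibrary(config$nPhantoms, size = config$imageSize,
                                 seed = childSeed(config$seed, "phantoms"))
  geom <- systemGeometry(config$nBins, config$nAngles,
                         c(config$imageSize, config$imageSize))
  sysmat <- buildSystemMatrix(geom)

  # one randomized parameter set = kinetics + input coefficients per tracer
  kinSets <- lapply(seq_along(config$tracers), function(ti) {
    tr <- config$tracers[[ti]]
    list(kin = sampleParameters(defaultKinetics(tr@name, 5L),
                                config$kineticCV, config$nParameterSets,
                                childSeed(config$seed, "kin", ti)),
         inp = sampleParameters(tr@inputParams, config$inputCV,
                                config$nParameterSets,
                                childSeed(config$seed, "inp", ti)))
  })

  for (g in seq_len(nGroups)) {
    ph <- phantoms[[manifest$phantom[g]]]
    s <- manifest$paramSet[g]
    sinos <- vector("list", 2L)
    for (ti in 1:2) {
      tr <- config$tracers[[ti]]
      kin <- kinSets[[ti]]$kin[[s]][seq_len(ph@nROIs), , drop = FALSE]
      img <- makeDynamicImage(ph, kin, tr, prot, decay = config$decay,
                              inputParams = kinSets[[ti]]$inp[[s]])
      clean <- forwardProject(img, sysmat)
      noisy <- addNoise(clean, config$countLevel, config$randomsFraction,
                        seed = childSeed(config$seed, "noise", g, ti))
      sinos[[ti]] <- noisy
      label <- osem(noisy, sysmat, config$osemIter, config$osemSubsets)
      label@tracer <- tr@name
      writeDynamicImage(label,
                        if (ti == 1) manifest$labelI[g] else manifest$labelII[g])
    }
    writeSinogram(combineTracers(sinos[[1]], sinos[[2]]), manifest$dual[g])
    if (verbose && g %% 10 == 0)
      message(sprintf("simulated %d / %d groups", g, nGroups))
  }
  attr(manifest, "phantoms") <- phantoms
  attr(manifest, "geometry") <- geom
  manifest
}

#' Compute and store normalization statistics on a dataset manifest
#'
#' Network inputs are standardized by the global scalar mean and standard
#' deviation of the *training* inputs only (no test-set leakage); labels
#' are divided by the configured constant (\code{labelScale}, 255 by
#' simulation convention). The statistics are stored on the manifest and
#' applied lazily when batches are loaded.
#'
#' @param manifest a manifest from [buildDataset()].
#' @return the manifest with a "norm" attribute (mean, sd, labelScale,
#'   partition provenance).
#' @export
normalizeDataset <- function(manifest) {
  config <- attr(manifest, "config")
  trainRows <- which(manifest$partition == "train")
  if (length(trainRows) == 0L) stop("training partition is empty")
  n <- 0; s1 <- 0; s2 <- 0
  for (r in trainRows) {
    x <- readSinogram(manifest$dual[r])@data
    n <- n + length(x); s1 <- s1 + sum(x); s2 <- s2 + sum(x^2)
  }
  m <- s1 / n
  v <- s2 / n - m^2
  if (v <= 0) stop("zero variance across training inputs; cannot standardize")
  attr(manifest, "norm") <- list(mean = m, sd = sqrt(v),
                                 labelScale = config$labelScale,
                                 from = "train")
  manifest
}

# Load one manifest row into normalized tensors:
# input (W,H,D) + labels (W,H,D) per tracer on the label scale.
loadGroupTensors <- function(manifest, row, targetW, anglePolicy) {
  norm <- attr(manifest, "norm")
  sino <- readSinogram(manifest$dual[row])
  x <- sinoToTensor(sino@data, targetW, anglePolicy)
  x <- (x - norm$mean) / norm$sd
  lI <- aperm(readDynamicImage(manifest$labelI[row])@data, c(2, 1, 3)) /
    norm$labelScale
  lII <- aperm(readDynamicImage(manifest$labelII[row])@data, c(2, 1, 3)) /
    norm$labelScale
  list(x = x, lI = lI, lII = lII)
}

batchTensor <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, dim = c(d[1:4], length(xs)))
  for (i in seq_along(xs)) out[, , , , i] <- xs[[i]]
  out
}

#' Train the multi-task reconstruction network
#'
#' Adam optimization of the frame-averaged two-tracer MSE/SSIM loss on
#' the normalized dataset. Per-epoch training and validation losses are
#' logged; the checkpoint with the lowest validation loss is kept.
#' Seeded end to end: reruns with the same config reproduce the epoch-1
#' loss exactly.
#'
#' @param manifest a normalized manifest ([normalizeDataset()]).
#' @param config the [experimentConfig()] used to build it.
#' @param verbose print per-epoch losses.
#' @return a trained [ReconModel-class]; \code{model@meta$log} holds the
#'   training log, \code{model@meta$norm} the normalization statistics.
#' @export
trainModel <- function(manifest, config, verbose = FALSE) {
  norm <- attr(manifest, "norm")
  if (is.null(norm)) stop("manifest is not normalized; run normalizeDataset()")
  spec <- lossSpec(alpha = config$alpha, beta = config$beta)
  targetW <- config$imageSize
  policy <- config$netConfig$anglePolicy
  trainRows <- which(manifest$partition == "train")
  valRows <- which(manifest$partition == "val")

  data <- lapply(seq_len(nrow(manifest)), function(r)
    loadGroupTensors(manifest, r, targetW, policy))

  model <- buildNetwork(config$netConfig, seed = childSeed(config$seed, "init"))
  net <- model@net
  state <- adamInit(net)
  bestNet <- net
  bestVal <- Inf
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  stepCount <- 0L
  cropW <- if (policy == "crop") targetW else NULL

  batchLoss <- function(net, rows, train) {
    x <- batchTensor(lapply(data[rows], `[[`, "x"))
    fw <- netForward(net, x, train = train)
    nb <- length(rows)
    tot <- 0
    dy1 <- array(0, dim(fw$y1)); dy2 <- array(0, dim(fw$y2))
    for (i in seq_len(nb)) {
      extract <- function(y) {
        arr <- array(y[, , , 1, i], dim(y)[1:3])
        if (!is.null(cropW) && dim(arr)[1] != cropW) {
          off <- (dim(arr)[1] - cropW) %/% 2
          arr[(off + 1):(off + cropW), , , drop = FALSE]
        } else arr
      }
      # the nonnegativity clamp is an inference-time output stage; the
      # loss sees the raw final-layer outputs so gradients stay alive
      y1 <- extract(fw$y1); y2 <- extract(fw$y2)
      lg <- lossTotalGrad(y1, data[[rows[i]]]$lI, y2, data[[rows[i]]]$lII,
                          spec)
      tot <- tot + lg$value
      if (train) {
        g1 <- lg$gradI / nb; g2 <- lg$gradII / nb
        if (!is.null(cropW) && dim(fw$y1)[1] != cropW) {
          off <- (dim(fw$y1)[1] - cropW) %/% 2
          dy1[(off + 1):(off + cropW), , , 1, i] <- g1
          dy2[(off + 1):(off + cropW), , , 1, i] <- g2
        } else {
          dy1[, , , 1, i] <- g1
          dy2[, , , 1, i] <- g2
        }
      }
    }
    list(loss = tot / nb, fw = fw, dy1 = dy1, dy2 = dy2)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- withSeed(childSeed(config$seed, "epoch", epoch),
                    sample(trainRows))
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0
    for (b in batches) {
      bl <- batchLoss(net, b, train = TRUE)
      if (!is.finite(bl$loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      net <- bl$fw$net  # batch-norm running stats updated in forward
      bw <- netBackward(net, bl$fw$cache, bl$dy1, bl$dy2)
      stepCount <- stepCount + 1L
      upd <- adamStep(net, bw$grads, state, lr = config$lr, t = stepCount,
                      weightDecay = config$weightDecay)
      net <- upd$net
      state <- upd$state
      epochLoss <- epochLoss + bl$loss * length(b)
    }
    epochLoss <- epochLoss / length(ord)
    valLoss <- if (length(valRows) > 0)
      batchLoss(net, valRows, train = FALSE)$loss else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epochLoss,
                                 val_loss = valLoss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, epochLoss,
                      valLoss))
    if (is.finite(valLoss) && valLoss < bestVal) {
      bestVal <- valLoss
      bestNet <- net
    }
  }
  if (!is.finite(bestVal)) bestNet <- net
  new("ReconModel", net = bestNet, config = unclass(config$netConfig),
      meta = list(seed = config$seed, norm = norm, log = log))
}

#' Extract per-ROI time-activity curves from a dynamic image
#'
#' Mean voxel value per frame within each phantom label, including the
#' background (label 0).
#'
#' @param image a [DynamicImage-class] on the phantom grid.
#' @param phantom the matching [Phantom-class].
#' @return data.frame with columns roi, frame, time_s, value.
#' @export
extractRoiTacs <- function(image, phantom) {
  d <- dim(image@data)
  if (!all(d[1:2] == dim(phantom@labelMap)))
    stop("image grid does not match the phantom")
  tmid <- midFrameTimes(image)
  rows <- list()
  for (r in 0:phantom@nROIs) {
    idx <- which(phantom@labelMap == r)
    vals <- vapply(seq_len(d[3]),
                   function(f) mean(image@data[, , f][idx]), numeric(1))
    rows[[r + 1L]] <- data.frame(roi = r, frame = seq_len(d[3]),
                                 time_s = tmid, value = vals)
  }
  do.call(rbind, rows)
}

#' Evaluate a trained model on the test partition
#'
#' Runs the trained network on every test-group dual-tracer sinogram and
#' scores both tracers against the OSEM labels with MSE, MS-SSIM and
#' PSNR; the naive split-half baseline (OSEM of the dual sinogram, halved)
#' is evaluated on the same groups for reference. Also extracts ROI TACs
#' (model vs label) for the first test group.
#'
#' @param model a trained [ReconModel-class].
#' @param manifest the normalized manifest the model was trained on.
#' @param config the [experimentConfig()].
#' @return list with \code{summary} (per tracer x method mean metrics),
#'   \code{perSample} (per-group rows), and \code{tacs} (ROI-TAC table
#'   for the first test group).
#' @export
runExperiment <- function(model, manifest, config) {
  testRows <- which(manifest$partition == "test")
  if (length(testRows) == 0L) stop("test partition is empty")
  geom <- attr(manifest, "geometry")
  if (is.null(geom))
    geom <- systemGeometry(config$nBins, config$nAngles,
                           c(config$imageSize, config$imageSize))
  sysmat <- buildSystemMatrix(geom)
  phantoms <- attr(manifest, "phantoms")

  perSample <- list()
  tacs <- NULL
  for (r in testRows) {
    dual <- readSinogram(manifest$dual[r])
    labI <- readDynamicImage(manifest$labelI[r])
    labII <- readDynamicImage(manifest$labelII[r])
    est <- reconForward(model, dual)
    base <- splitHalfBaseline(osem(dual, sysmat, config$osemIter,
                                   config$osemSubsets))
    for (meth in c("multitask", "splithalf")) {
      pair <- if (meth == "multitask") est else base
      for (ti in 1:2) {
        ev <- evaluatePair(pair[[ti]], if (ti == 1) labI else labII)
        m <- ev[ev$frame == "mean", ]
        perSample[[length(perSample) + 1L]] <- data.frame(
          group = manifest$group[r], method = meth,
          tracer = c("I", "II")[ti], mse = m$mse, ms_ssim = m$ms_ssim,
          psnr = m$psnr)
      }
    }
    if (is.null(tacs) && !is.null(phantoms)) {
      ph <- phantoms[[manifest$phantom[r]]]
      tacs <- rbind(
        cbind(extractRoiTacs(est$I, ph), tracer = "I", source = "model"),
        cbind(extractRoiTacs(labI, ph), tracer = "I", source = "label"),
        cbind(extractRoiTacs(est$II, ph), tracer = "II", source = "model"),
        cbind(extractRoiTacs(labII, ph), tracer = "II", source = "label"))
    }
  }
  perSample <- do.call(rbind, perSample)
  summary <- stats::aggregate(cbind(mse, ms_ssim, psnr) ~ method + tracer,
                              data = perSample, FUN = mean)
  list(summary = summary, perSample = perSample, tacs = tacs)
}
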