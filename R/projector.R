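#' @include AllGenerics.R
NULL

#' Define a parallel-beam sinogram geometry
#'
#' Angles are uniform over [0, 180) degrees. By default the radial bins
#' span the image diagonal field of view, i.e.
#' \code{binWidthMM = sqrt(2) * H * pixelSizeMM / nBins}, so every pixel
#' projects inside the detector at every angle.
#'
#' @param nBins number of radial bins (default 128).
#' @param nAngles number of angles (default 160).
#' @param imageSize image grid (H, W); square grids expected.
#' @param pixelSizeMM pixel size in mm (square pixels; default 2.2).
#' @param binWidthMM radial bin width in mm; default spans the diagonal.
#' @return a [SystemGeometry-class].
#' @examples
#' systemGeometry()                      # 128 bins x 160 angles
#' systemGeometry(32, 40, c(32, 32))    # desk scale
#' @export
systemGeometry <- function(nBins = 128L, nAngles = 160L,
                           imageSize = c(128L, 128L), pixelSizeMM = 2.2,
                           binWidthMM = NULL) {
  if (is.null(binWidthMM))
    binWidthMM <- sqrt(2) * max(imageSize) * pixelSizeMM / nBins
  new("SystemGeometry", nBins = as.integer(nBins),
      nAngles = as.integer(nAngles), imageSize = as.integer(imageSize),
      pixelSizeMM = as.numeric(pixelSizeMM),
      binWidthMM = as.numeric(binWidthMM))
}

setMethod("show", "SystemGeometry", function(object) {
  cat(sprintf("SystemGeometry: %d bins x %d angles, image %d x %d, pixel %.3g mm, bin %.3g mm\n",
              object@nBins, object@nAngles, object@imageSize[1],
              object@imageSize[2], object@pixelSizeMM, object@binWidthMM))
})

#' Build the strip-integral system matrix
#'
#' Entry (i, j) is the intersection area of detector strip i with pixel j
#' divided by the strip width (the strip-averaged intersection length in
#' mm), computed in closed form from the trapezoidal projection profile of
#' a square pixel. No attenuation, scatter or detector-efficiency
#' modelling. Deterministic: the same geometry always yields the same
#' matrix.
#'
#' @param geom a [SystemGeometry-class].
#' @return a [SystemMatrix-class] whose \code{G} slot is a sparse
#'   dgCMatrix with nBins*nAngles rows (bin fastest) and H*W columns
#'   (column-major pixel order).
#' @examples
#' G <- buildSystemMatrix(systemGeometry(32, 20, c(16, 16)))
#' dim(G@G)
#' @export
buildSystemMatrix <- function(geom) {
  h <- geom@imageSize[1]; w <- geom@imageSize[2]
  tr <- cpp_strip_sysmat(h, w, geom@pixelSizeMM, geom@nBins, geom@nAngles,
                         geom@binWidthMM)
  G <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(geom@nBins * geom@nAngles, h * w))
  new("SystemMatrix", G = G, geometry = geom)
}

#' @rdname geometry
#' @export
setMethod("geometry", "SystemMatrix", function(x) x@geometry)

setMethod("show", "SystemMatrix", function(object) {
  g <- object@geometry
  cat(sprintf("SystemMatrix: %d x %d sparse (%.2f%% nonzero), %d bins x %d angles\n",
              nrow(object@G), ncol(object@G),
              100 * Matrix::nnzero(object@G) / prod(dim(object@G)),
              g@nBins, g@nAngles))
})

#' Forward project a dynamic image
#'
#' Frame-wise matrix-vector product \eqn{y(t) = G x(t)} (the noise-free
#' imaging model). Linear and nonnegativity-preserving.
#'
#' @param image a [DynamicImage-class].
#' @param sysmat a [SystemMatrix-class] with matching image size.
#' @return a [DynamicSinogram-class] of expected projections.
#' @export
forwardProject <- function(image, sysmat) {
  g <- sysmat@geometry
  d <- dim(image@data)
  if (d[1] != g@imageSize[1] || d[2] != g@imageSize[2])
    stop("image size does not match the system matrix geometry")
  nF <- d[3]
  X <- matrix(image@data, prod(g@imageSize), nF)
  Y <- as.matrix(sysmat@G %*% X)
  new("DynamicSinogram",
      data = array(Y, dim = c(g@nBins, g@nAngles, nF)),
      geometry = g, protocol = image@protocol)
}

#' Back project a dynamic sinogram (adjoint of forwardProject)
#'
#' Frame-wise \eqn{G^T y}; used by OSEM and available for diagnostics.
#'
#' @param sino a [DynamicSinogram-class].
#' @param sysmat a [SystemMatrix-class].
#' @param protocolCheck check that geometries match (default TRUE).
#' @return a [DynamicImage-class] (not normalized).
#' @export
backProject <- function(sino, sysmat, protocolCheck = TRUE) {
  g <- sysmat@geometry
  if (protocolCheck &&
      (sino@geometry@nBins != g@nBins || sino@geometry@nAngles != g@nAngles))
    stop("sinogram geometry does not match the system matrix")
  nF <- dim(sino@data)[3]
  Y <- matrix(sino@data, g@nBins * g@nAngles, nF)
  X <- as.matrix(Matrix::crossprod(sysmat@G, Y))
  new("DynamicImage",
      data = array(pmax(X, 0), dim = c(g@imageSize, nF)),
      protocol = sino@protocol, tracer = "backprojection")
}

#' Add Poisson counting noise and a randoms background
#'
#' Each frame is scaled so its expected true counts equal
#' \code{countLevel * (1 - randomsFraction)}; a spatially uniform randoms
#' background totalling \code{countLevel * randomsFraction} is added; the
#' sum is Poisson-sampled; and the result is returned on the original
#' intensity scale. Randoms are not subtracted afterwards. Frames with
#' zero total activity stay zero (scaling is undefined there) unless a
#' randoms background is requested, in which case it is added on the
#' count scale directly.
#'
#' @param sino a noise-free [DynamicSinogram-class].
#' @param countLevel expected total counts per frame (> 0); default 5e5.
#' @param randomsFraction fraction of counts from randoms, in [0, 1);
#'   default 0.2.
#' @param seed RNG seed.
#' @return a noisy [DynamicSinogram-class] on the input intensity scale.
#' @export
addNoise <- function(sino, countLevel = 5e5, randomsFraction = 0.2,
                     seed = NULL) {
  stopifnot_scalar(countLevel, "countLevel")
  if (countLevel <= 0) stop("'countLevel' must be positive")
  if (randomsFraction < 0 || randomsFraction >= 1)
    stop("'randomsFraction' must be in [0, 1)")
  g <- sino@geometry
  nF <- dim(sino@data)[3]
  nbin <- g@nBins * g@nAngles
  out <- sino@data
  withSeed(seed, {
    for (f in seq_len(nF)) {
      frame <- sino@data[, , f]
      tot <- sum(frame)
      bgPerBin <- countLevel * randomsFraction / nbin
      if (tot <= 0) {
        if (randomsFraction > 0)
          out[, , f] <- stats::rpois(nbin, rep(bgPerBin, nbin))
        next
      }
      sc <- countLevel * (1 - randomsFraction) / tot
      lam <- frame * sc + bgPerBin
      out[, , f] <- stats::rpois(nbin, lam) / sc
    }
  })
  new("DynamicSinogram", data = out, geometry = g, protocol = sino@protocol)
}

#' Combine two single-tracer sinograms into a dual-tracer sinogram
#'
#' The dual-tracer dynamic sinogram is the element-wise sum of the two
#' single-tracer dynamic sinograms (both tracers emit identical 511-keV
#' photon pairs, so the detector simply counts their sum).
#'
#' @param sinoI,sinoII [DynamicSinogram-class] objects on identical
#'   geometry and protocol.
#' @return the summed [DynamicSinogram-class].
#' @export
combineTracers <- function(sinoI, sinoII) {
  gi <- sinoI@geometry; gii <- sinoII@geometry
  if (gi@nBins != gii@nBins || gi@nAngles != gii@nAngles ||
      any(gi@imageSize != gii@imageSize))
    stop("sinogram geometries do not match")
  if (!isTRUE(all.equal(frameDurations(sinoI@protocol),
                        frameDurations(sinoII@protocol))))
    stop("scan protocols do not match")
  new("DynamicSinogram", data = sinoI@data + sinoII@data,
      geometry = gi, protocol = sinoI@protocol)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "DynamicSinogram", function(x) dim(x@data)[3])
#' @rdname midFrameTimes
#' @export
setMethod("midFrameTimes", "DynamicSinogram",
          function(x) midFrameTimes(x@protocol))
#' @rdname frameDurations
#' @export
setMethod("frameDurations", "DynamicSinogram",
          function(x) frameDurations(x@protocol))
#' @rdname frameEdges
#' @export
setMethod("frameEdges", "DynamicSinogram",
          function(x) frameEdges(x@protocol))
#' @rdname totalDuration
#' @export
setMethod("totalDuration", "DynamicSinogram",
          function(x) totalDuration(x@protocol))
#' @rdname dataArray
#' @export
setMethod("dataArray", "DynamicSinogram", function(x) x@data)
#' @rdname protocol
#' @export
setMethod("protocol", "DynamicSinogram", function(x) x@protocol)
#' @rdname geometry
#' @export
setMethod("geometry", "DynamicSinogram", function(x) x@geometry)

setMethod("show", "DynamicSinogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicSinogram: %d bins x %d angles x %d frames, total %.4g\n",
              d[1], d[2], d[3], sum(object@data)))
})
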