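#' @include utils.R
#' @importClassesFrom Matrix dgCMatrix
NULL

#' ScanProtocol: ordered frame durations of a dynamic acquisition
#'
#' Holds the frame durations (seconds) of a dynamic PET scan. Frame edges
#' and mid-frame times are derived from the cumulative durations.
#'
#' @slot frameDurations numeric vector of frame durations in seconds, all
#'   positive.
#' @seealso [parseProtocol()], [nFrames()], [midFrameTimes()]
#' @exportClass ScanProtocol
setClass("ScanProtocol",
         representation(frameDurations = "numeric"),
         validity = function(object) {
           d <- object@frameDurations
           if (length(d) < 1L) return("at least one frame is required")
           if (any(!is.finite(d)) || any(d <= 0))
             return("all frame durations must be positive and finite")
           TRUE
         })

#' Phantom: 2D integer ROI label map with pixel geometry
#'
#' The spatial substrate of the simulation: an H x W integer grid where 0
#' is background and 1..R index regions of interest (ROIs). Label values
#' always form the contiguous set \{0, ..., R\} with every ROI nonempty.
#'
#' @slot labelMap integer matrix (H x W) of ROI labels.
#' @slot nROIs number of ROIs R.
#' @slot pixelSizeMM in-plane pixel size (dx, dy) in mm.
#' @slot sliceThicknessMM slice thickness in mm.
#' @seealso [makePhantom()], [makePhantomLibrary()]
#' @exportClass Phantom
setClass("Phantom",
         representation(labelMap = "matrix", nROIs = "integer",
                        pixelSizeMM = "numeric", sliceThicknessMM = "numeric"),
         validity = function(object) {
           lm <- object@labelMap
           R <- object@nROIs
           if (!is.numeric(lm)) return("labelMap must be numeric/integer")
           labs <- sort(unique(as.integer(lm)))
           if (!identical(labs, 0:R))
             return(sprintf("label values must be exactly {0..%d}", R))
           if (length(object@pixelSizeMM) != 2L || any(object@pixelSizeMM <= 0))
             return("pixelSizeMM must be two positive numbers")
           if (object@sliceThicknessMM <= 0)
             return("sliceThicknessMM must be positive")
           TRUE
         })

#' TracerSpec: radiotracer identity, half-life and plasma input model
#'
#' @slot name tracer name, e.g. "FDG", "FMZ", "Acetate".
#' @slot halfLifeS physical half-life in seconds.
#' @slot inputModel identifier of the plasma input functional form
#'   (currently "feng": a Feng-type multi-exponential bolus).
#' @slot inputParams coefficients of the input model; for "feng" these are
#'   (A1, A2, A3, l1, l2, l3) with amplitudes in kBq/mL (A1 in
#'   kBq/mL/min) and rates in 1/min.
#' @seealso [defaultTracer()], [inputFunction()]
#' @exportClass TracerSpec
setClass("TracerSpec",
         representation(name = "character", halfLifeS = "numeric",
                        inputModel = "character", inputParams = "numeric"),
         validity = function(object) {
           if (object@halfLifeS <= 0) return("halfLifeS must be positive")
           if (any(!is.finite(object@inputParams)))
             return("inputParams must be finite")
           TRUE
         })

#' TAC: a time-activity curve on a fine time grid
#'
#' @slot time time grid in seconds, strictly increasing, starting at 0.
#' @slot values activity concentration (kBq/mL), nonnegative.
#' @exportClass TAC
setClass("TAC",
         representation(time = "numeric", values = "numeric"),
         validity = function(object) {
           if (length(object@time) != length(object@values))
             return("time and values must have equal length")
           if (object@time[1] != 0) return("time grid must start at 0")
           if (any(diff(object@time) <= 0))
             return("time grid must be strictly increasing")
           if (any(object@values < -1e-9))
             return("TAC values must be nonnegative")
           TRUE
         })

#' DynamicImage: a dynamic (multi-frame) activity image sequence
#'
#' Activity concentration per voxel and frame. The array is stored as
#' H x W x F (frame-contiguous slices); conceptually the object is the
#' frame sequence x(t_1), ..., x(t_F).
#'
#' @slot data numeric array H x W x F, nonnegative and finite.
#' @slot protocol the [ScanProtocol-class] defining the F frames.
#' @slot tracer tracer name tag.
#' @seealso [makeDynamicImage()], [osem()]
#' @exportClass DynamicImage
setClass("DynamicImage",
         representation(data = "array", protocol = "ScanProtocol",
                        tracer = "character"),
         validity = function(object) {
           d <- dim(object@data)
           if (length(d) != 3L) return("data must be an H x W x F array")
           if (d[3] != length(object@protocol@frameDurations))
             return("frame count does not match protocol")
           if (any(!is.finite(object@data))) return("data must be finite")
           if (any(object@data < 0)) return("data must be nonnegative")
           TRUE
         })

#' SystemGeometry: parallel-beam sinogram geometry
#'
#' @slot nBins number of radial bins.
#' @slot nAngles number of projection angles, uniform over [0, 180).
#' @slot imageSize (H, W) of the image grid.
#' @slot pixelSizeMM in-plane pixel size in mm (square pixels).
#' @slot binWidthMM radial bin (= strip) width in mm.
#' @seealso [systemGeometry()], [buildSystemMatrix()]
#' @exportClass SystemGeometry
setClass("SystemGeometry",
         representation(nBins = "integer", nAngles = "integer",
                        imageSize = "integer", pixelSizeMM = "numeric",
                        binWidthMM = "numeric"),
         validity = function(object) {
           if (object@nBins < 1L || object@nAngles < 1L)
             return("nBins and nAngles must be >= 1")
           if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
             return("imageSize must be two positive integers")
           if (object@pixelSizeMM <= 0 || object@binWidthMM <= 0)
             return("pixelSizeMM and binWidthMM must be positive")
           TRUE
         })

#' SystemMatrix: sparse strip-integral projection operator
#'
#' Sparse nonnegative matrix G with nBins*nAngles rows and H*W columns;
#' entry (i, j) is the intersection area of detector strip i with pixel j
#' divided by the strip width (strip-averaged intersection length, mm).
#'
#' @slot G sparse Matrix (dgCMatrix).
#' @slot geometry the [SystemGeometry-class] it was built from.
#' @seealso [buildSystemMatrix()], [forwardProject()]
#' @exportClass SystemMatrix
setClass("SystemMatrix",
         representation(G = "dgCMatrix", geometry = "SystemGeometry"),
         validity = function(object) {
           g <- object@geometry
           if (nrow(object@G) != g@nBins * g@nAngles)
             return("row count must equal nBins * nAngles")
           if (ncol(object@G) != prod(g@imageSize))
             return("column count must equal H * W")
           TRUE
         })

#' DynamicSinogram: dynamic projection data
#'
#' Counts or expected counts per radial bin, angle and frame, stored as a
#' nBins x nAngles x F array.
#'
#' @slot data numeric array nBins x nAngles x F, nonnegative, finite.
#' @slot geometry the [SystemGeometry-class].
#' @slot protocol the [ScanProtocol-class].
#' @seealso [forwardProject()], [addNoise()], [combineTracers()]
#' @exportClass DynamicSinogram
setClass("DynamicSinogram",
         representation(data = "array", geometry = "SystemGeometry",
                        protocol = "ScanProtocol"),
         validity = function(object) {
           d <- dim(object@data)
           if (length(d) != 3L) return("data must be nBins x nAngles x F")
           if (d[1] != object@geometry@nBins || d[2] != object@geometry@nAngles)
             return("data shape does not match geometry")
           if (d[3] != length(object@protocol@frameDurations))
             return("frame count does not match protocol")
           if (any(!is.finite(object@data))) return("data must be finite")
           if (any(object@data < 0)) return("data must be nonnegative")
           TRUE
         })

#' ReconModel: the multi-task reconstruction network
#'
#' Weights and architecture of the multi-task CNN: a shared 3D
#' convolutional encoder over the dual-tracer dynamic sinogram and two
#' parallel decoders emitting the two single-tracer dynamic images.
#'
#' @slot net list with elements `encoder`, `dec1`, `dec2`, each a list of
#'   layer objects (see [buildNetwork()]).
#' @slot config the network configuration list ([networkConfig()]).
#' @slot meta training metadata: seed, normalization statistics, training
#'   log.
#' @seealso [buildNetwork()], [reconForward()], [trainModel()]
#' @exportClass ReconModel
setClass("ReconModel",
         representation(net = "list", config = "list", meta = "list"))
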