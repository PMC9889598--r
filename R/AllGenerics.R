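#' @include AllClasses.R
NULL

#' Number of frames of a dynamic object
#' @param x a ScanProtocol, DynamicImage or DynamicSinogram.
#' @return integer frame count F.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Mid-frame times in seconds
#' @param x a ScanProtocol, DynamicImage or DynamicSinogram.
#' @return numeric vector t_f = start_f + duration_f / 2.
#' @export
setGeneric("midFrameTimes", function(x) standardGeneric("midFrameTimes"))

#' Frame durations in seconds
#' @param x a ScanProtocol, DynamicImage or DynamicSinogram.
#' @return numeric vector of durations.
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' Frame start/end edges in seconds
#' @param x a ScanProtocol, DynamicImage or DynamicSinogram.
#' @return F x 2 matrix with columns start, end.
#' @export
setGeneric("frameEdges", function(x) standardGeneric("frameEdges"))

#' Total scan duration in seconds
#' @param x a ScanProtocol, DynamicImage or DynamicSinogram.
#' @return scalar total duration.
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' ROI label map of a phantom
#' @param x a Phantom.
#' @return integer H x W matrix (0 = background).
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' Number of ROIs of a phantom
#' @param x a Phantom.
#' @return integer R.
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))

#' Underlying data array
#'
#' The raw array of a dynamic object: H x W x F for a
#' [DynamicImage-class], nBins x nAngles x F for a
#' [DynamicSinogram-class].
#' @param x a DynamicImage or DynamicSinogram.
#' @return numeric array.
#' @export
setGeneric("dataArray", function(x) standardGeneric("dataArray"))

#' Scan protocol of a dynamic object
#' @param x a DynamicImage or DynamicSinogram.
#' @return a [ScanProtocol-class].
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' Sinogram geometry of an object
#' @param x a DynamicSinogram or SystemMatrix.
#' @return a [SystemGeometry-class].
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
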