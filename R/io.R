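#' @include projector.R
NULL

protocolToList <- function(p) list(frame_durations_s = p@frameDurations)
protocolFromList <- function(l) scanProtocol(unlist(l$frame_durations_s))

#' Write / read a dynamic image as NIfTI + YAML sidecar
#'
#' The activity array is stored as an H x W x F NIfTI volume (frame as
#' the last dimension); protocol and tracer go to a YAML sidecar.
#'
#' @param image a [DynamicImage-class].
#' @param path output path (".nii" or ".nii.gz").
#' @return \code{writeDynamicImage}: the path, invisibly;
#'   \code{readDynamicImage}: a [DynamicImage-class].
#' @export
writeDynamicImage <- function(image, path) {
  RNifti::writeNifti(RNifti::asNifti(image@data), path)
  yaml::write_yaml(c(protocolToList(image@protocol),
                     list(tracer = image@tracer)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeDynamicImage
#' @export
readDynamicImage <- function(path) {
  arr <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  new("DynamicImage", data = array(as.numeric(arr), dim(arr)),
      protocol = protocolFromList(meta), tracer = meta$tracer)
}

#' Write / read a dynamic sinogram as NIfTI + YAML sidecar
#'
#' The count array is stored as nBins x nAngles x F; geometry and
#' protocol go to a YAML sidecar.
#'
#' @param sino a [DynamicSinogram-class].
#' @param path output path (".nii" or ".nii.gz").
#' @return \code{writeSinogram}: the path, invisibly;
#'   \code{readSinogram}: a [DynamicSinogram-class].
#' @export
writeSinogram <- function(sino, path) {
  g <- sino@geometry
  RNifti::writeNifti(RNifti::asNifti(sino@data), path)
  yaml::write_yaml(c(protocolToList(sino@protocol),
                     list(geometry = list(
                       n_bins = g@nBins, n_angles = g@nAngles,
                       image_size = as.integer(g@imageSize),
                       pixel_size_mm = g@pixelSizeMM,
                       bin_width_mm = g@binWidthMM))),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  arr <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  gm <- meta$geometry
  g <- systemGeometry(gm$n_bins, gm$n_angles, unlist(gm$image_size),
                      gm$pixel_size_mm, gm$bin_width_mm)
  new("DynamicSinogram", data = array(as.numeric(arr), dim(arr)),
      geometry = g, protocol = protocolFromList(meta))
}
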