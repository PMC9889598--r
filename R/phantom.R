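#' @include AllGenerics.R
NULL

# Rasterize a (possibly rotated) ellipse or annulus on an n x n grid.
# Returns a logical mask. Coordinates are in pixel units, centre-origin.
ellipseMask <- function(n, cx, cy, a, b, phi = 0, innerFrac = 0) {
  xs <- seq_len(n) - (n + 1) / 2
  X <- matrix(xs, n, n, byrow = TRUE) - cx   # column coordinate
  Y <- matrix(xs, n, n, byrow = FALSE) - cy  # row coordinate
  U <- cos(phi) * X + sin(phi) * Y
  V <- -sin(phi) * X + cos(phi) * Y
  r2 <- (U / a)^2 + (V / b)^2
  m <- r2 <= 1
  if (innerFrac > 0) m <- m & (r2 >= innerFrac^2)
  m
}

# One deterministic attempt at a label map; may leave a label empty.
drawLabelMap <- function(nROIs, size) {
  lab <- matrix(0L, size, size)
  # head-like outer boundary: large quasi-elliptical region = ROI 1
  head_a <- size * stats::runif(1, 0.38, 0.45)
  head_b <- size * stats::runif(1, 0.32, 0.42)
  phi0 <- stats::runif(1, 0, pi)
  lab[ellipseMask(size, 0, 0, head_a, head_b, phi0)] <- 1L
  if (nROIs > 1L) {
    # inner ROIs: ellipses/annuli, drawn largest-first; later ROIs
    # overwrite earlier labels where they overlap
    scales <- sort(stats::runif(nROIs - 1L, 0.12, 0.55), decreasing = TRUE)
    for (k in seq_len(nROIs - 1L)) {
      s <- scales[k]
      a <- max(2.2, head_a * s)
      b <- max(2.2, head_b * s * stats::runif(1, 0.6, 1.1))
      rho <- stats::runif(1, 0, 0.55)
      ang <- stats::runif(1, 0, 2 * pi)
      cx <- rho * head_a * cos(ang) * 0.8
      cy <- rho * head_b * sin(ang) * 0.8
      inner <- if (k %% 2L == 0L) stats::runif(1, 0.35, 0.6) else 0
      m <- ellipseMask(size, cx, cy, a, b, stats::runif(1, 0, pi), inner)
      m <- m & lab > 0L   # keep ROIs inside the head
      lab[m] <- k + 1L
    }
  }
  lab
}

#' Generate a multi-ROI phantom
#'
#' Draws a 2D phantom with a head-like outer boundary and \code{nROIs}
#' nested/overlapping smooth regions (ellipses and annuli). Later ROIs
#' overwrite earlier labels where they overlap, so the label map is always
#' a strict partition into \{0, ..., nROIs\}. Generation is deterministic
#' for a fixed seed; internally candidates are redrawn until every label
#' is nonempty (at least 4 pixels).
#'
#' @param nROIs number of ROIs, between 2 and 5.
#' @param size image side length in pixels (square grid), >= 16.
#' @param seed RNG seed.
#' @param pixelSizeMM in-plane pixel size in mm, default c(2.2, 2.2).
#' @param sliceThicknessMM slice thickness in mm, default 1.4.
#' @return a [Phantom-class].
#' @examples
#' ph <- makePhantom(3, size = 64, seed = 1)
#' table(labelMap(ph))
#' @export
makePhantom <- function(nROIs, size = 128L, seed = 1L,
                        pixelSizeMM = c(2.2, 2.2), sliceThicknessMM = 1.4) {
  if (!is.numeric(nROIs) || length(nROIs) != 1L || nROIs < 2 || nROIs > 5)
    stop("'nROIs' must be between 2 and 5")
  stopifnot_scalar(size, "size", lower = 16)
  nROIs <- as.integer(nROIs); size <- as.integer(size)
  lab <- withSeed(seed, {
    minArea <- max(4L, (size %/% 16L)^2)
    res <- NULL
    for (attempt in 1:200) {
      cand <- drawLabelMap(nROIs, size)
      counts <- tabulate(as.integer(cand) + 1L, nbins = nROIs + 1L)
      if (all(counts[-1] >= minArea)) { res <- cand; break }
    }
    if (is.null(res))
      stop("failed to draw a phantom with all ROIs nonempty")
    res
  })
  new("Phantom", labelMap = lab, nROIs = nROIs,
      pixelSizeMM = as.numeric(pixelSizeMM),
      sliceThicknessMM = as.numeric(sliceThicknessMM))
}

#' Generate a library of phantoms
#'
#' ROI counts cycle over 2, 3, 4, 5 along the list; each phantom gets a
#' seed derived from \code{seed} and its index, so the library is
#' reproducible as a whole.
#'
#' @param nPhantoms number of phantoms (>= 1).
#' @param size image side length in pixels.
#' @param seed master RNG seed.
#' @param ... passed on to [makePhantom()].
#' @return list of [Phantom-class] objects.
#' @examples
#' lib <- makePhantomLibrary(4, size = 32, seed = 0)
#' vapply(lib, nROIs, integer(1))  # 2 3 4 5
#' @export
makePhantomLibrary <- function(nPhantoms, size = 128L, seed = 0L, ...) {
  stopifnot_scalar(nPhantoms, "nPhantoms", lower = 1)
  lapply(seq_len(nPhantoms), function(i) {
    makePhantom(2L + (i - 1L) %% 4L, size = size,
                seed = childSeed(seed, "phantom", i), ...)
  })
}

#' @rdname labelMap
#' @export
setMethod("labelMap", "Phantom", function(x) x@labelMap)

#' @rdname nROIs
#' @export
setMethod("nROIs", "Phantom", function(x) x@nROIs)

setMethod("show", "Phantom", function(object) {
  d <- dim(object@labelMap)
  cat(sprintf("Phantom: %d x %d pixels, %d ROIs, pixel %.2g x %.2g mm, slice %.2g mm\n",
              d[1], d[2], object@nROIs, object@pixelSizeMM[1],
              object@pixelSizeMM[2], object@sliceThicknessMM))
  counts <- tabulate(as.integer(object@labelMap) + 1L,
                     nbins = object@nROIs + 1L)
  cat("  pixels per label:",
      paste(sprintf("%d:%d", 0:object@nROIs, counts), collapse = " "), "\n")
})

#' Write / read a phantom as NIfTI + YAML sidecar
#'
#' The label map is stored as a single-slice NIfTI integer volume; the ROI
#' count and geometry go to a YAML sidecar next to it.
#'
#' @param phantom a [Phantom-class].
#' @param path output NIfTI path (".nii"); sidecar gets ".yaml" appended.
#' @return \code{writePhantom}: the path, invisibly. \code{readPhantom}:
#'   a [Phantom-class].
#' @export
writePhantom <- function(phantom, path) {
  arr <- array(phantom@labelMap, dim = c(dim(phantom@labelMap), 1L))
  img <- RNifti::asNifti(arr,
                         pixdim = c(phantom@pixelSizeMM,
                                    phantom@sliceThicknessMM))
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(n_rois = phantom@nROIs,
                        pixel_size_mm = phantom@pixelSizeMM,
                        slice_thickness_mm = phantom@sliceThicknessMM),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writePhantom
#' @param path path written by \code{writePhantom}.
#' @export
readPhantom <- function(path) {
  arr <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  new("Phantom", labelMap = matrix(as.integer(arr), dim(arr)[1], dim(arr)[2]),
      nROIs = as.integer(meta$n_rois),
      pixelSizeMM = as.numeric(meta$pixel_size_mm),
      sliceThicknessMM = as.numeric(meta$slice_thickness_mm))
}
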