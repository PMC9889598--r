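#' @include projector.R
NULL

#' Ordered-subsets expectation maximization (OSEM) reconstruction
#'
#' Frame-wise OSEM with the standard multiplicative update
#' \deqn{x_j \leftarrow x_j \cdot
#'   \frac{\sum_{i \in S} g_{ij}\, y_i / (Gx)_i}{\sum_{i \in S} g_{ij}}}
#' initialized from a uniform positive image. Angles are assigned to
#' subsets round-robin (angle index mod nSubsets) and subsets are
#' processed in fixed order, so the result is deterministic. Bins with
#' \eqn{(Gx)_i = 0} contribute nothing (guarded ratio); pixels with zero
#' subset sensitivity are frozen at 0. No corrections, normalization or
#' post-filtering are applied.
#'
#' @param sino a [DynamicSinogram-class] of counts.
#' @param sysmat a [SystemMatrix-class] with matching geometry.
#' @param nIter number of full iterations (default 6).
#' @param nSubsets number of angular subsets (default 5).
#' @param init initial pixel value (default 1), or a full initial image
#'   (H x W array).
#' @return a [DynamicImage-class].
#' @examples
#' geom <- systemGeometry(32, 20, c(16, 16))
#' sm <- buildSystemMatrix(geom)
#' @export
osem <- function(sino, sysmat, nIter = 6L, nSubsets = 5L, init = 1) {
  g <- sysmat@geometry
  if (sino@geometry@nBins != g@nBins || sino@geometry@nAngles != g@nAngles)
    stop("sinogram geometry does not match the system matrix")
  stopifnot_scalar(nIter, "nIter", lower = 1)
  stopifnot_scalar(nSubsets, "nSubsets", lower = 1)
  if (nSubsets > g@nAngles) stop("more subsets than angles")

  nF <- dim(sino@data)[3]
  npix <- prod(g@imageSize)
  if (sum(sino@data) == 0) {
    warning("all-zero sinogram: returning a zero image")
    return(new("DynamicImage", data = array(0, dim = c(g@imageSize, nF)),
               protocol = sino@protocol, tracer = "osem"))
  }

  # round-robin angle subsets, fixed processing order 0..nSubsets-1
  subsetRows <- lapply(seq_len(nSubsets) - 1L, function(s) {
    ang <- which((seq_len(g@nAngles) - 1L) %% nSubsets == s)
    as.vector(outer(seq_len(g@nBins), (ang - 1L) * g@nBins, "+"))
  })
  Gs <- lapply(subsetRows, function(r) sysmat@G[r, , drop = FALSE])
  sens <- lapply(Gs, function(Gsub) as.numeric(Matrix::colSums(Gsub)))
  alive <- lapply(sens, function(s) s > 0)

  out <- array(0, dim = c(g@imageSize, nF))
  for (f in seq_len(nF)) {
    y <- as.numeric(sino@data[, , f])
    x <- if (length(init) == 1L) rep(as.numeric(init), npix)
         else as.numeric(init)
    if (length(x) != npix) stop("'init' must be scalar or one image")
    for (it in seq_len(nIter)) {
      for (s in seq_len(nSubsets)) {
        ys <- y[subsetRows[[s]]]
        q <- as.numeric(Gs[[s]] %*% x)
        ratio <- ifelse(q > 0, ys / q, 0)
        bp <- as.numeric(Matrix::crossprod(Gs[[s]], ratio))
        upd <- x
        a <- alive[[s]]
        upd[a] <- x[a] * bp[a] / sens[[s]][a]
        upd[!a] <- 0
        x <- upd
      }
    }
    out[, , f] <- x
  }
  new("DynamicImage", data = out, protocol = sino@protocol, tracer = "osem")
}

#' Poisson log-likelihood of sinogram data under an image
#'
#' \eqn{\sum_i [y_i \log (Gx)_i - (Gx)_i]} with the convention
#' \eqn{0 \log 0 = 0}; bins with \eqn{(Gx)_i = 0} but \eqn{y_i > 0}
#' contribute -Inf. Used to monitor EM convergence.
#'
#' @param sino a single-frame slice or [DynamicSinogram-class].
#' @param image matching [DynamicImage-class].
#' @param sysmat the [SystemMatrix-class].
#' @return scalar log-likelihood summed over frames (constant terms
#'   dropped).
#' @export
poissonLogLik <- function(sino, image, sysmat) {
  nF <- dim(sino@data)[3]
  ll <- 0
  for (f in seq_len(nF)) {
    y <- as.numeric(sino@data[, , f])
    q <- as.numeric(sysmat@G %*% as.numeric(image@data[, , f]))
    term <- numeric(length(y))
    pos <- y > 0
    term[pos] <- y[pos] * log(ifelse(q[pos] > 0, q[pos], NA)) - q[pos]
    term[pos][is.na(term[pos])] <- -Inf
    term[!pos] <- -q[!pos]
    ll <- ll + sum(term)
  }
  ll
}

#' Naive split-half dual-tracer baseline
#'
#' Represents total ignorance of tracer identity: given a reconstruction
#' of the dual-tracer sinogram, assigns half of the activity to each
#' tracer. The outputs sum to the input exactly. Any method that learns
#' anything about the tracers should beat this reference.
#'
#' @param dualRecon a [DynamicImage-class] reconstructed from the
#'   dual-tracer sinogram.
#' @return list of two [DynamicImage-class] objects (tracer I, tracer II),
#'   each \code{dualRecon / 2}.
#' @export
splitHalfBaseline <- function(dualRecon) {
  half <- dualRecon
  half@data <- dualRecon@data / 2
  list(I = half, II = half)
}
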