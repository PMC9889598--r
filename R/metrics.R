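#' @include loss.R
NULL

#' Mean squared error between two images or image sequences
#'
#' @param xhat,x numeric arrays of identical shape.
#' @return mean of squared differences.
#' @export
mse <- function(xhat, x) {
  xhat <- frameStack(xhat); x <- frameStack(x)
  if (!all(dim(xhat) == dim(x))) stop("shape mismatch")
  mean((xhat - x)^2)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' \deqn{\mathrm{PSNR}(\hat x, x) = 10 \log_{10}
#'   \left[ x_{\max}^2 / \mathrm{MSE}(\hat x, x) \right]}
#' where \eqn{x_{\max}} is the maximum of the reference image \code{x}.
#' Identical images have zero MSE; the function then returns \code{Inf}
#' with a warning rather than a silent finite number.
#'
#' @param xhat estimated image (matrix or array).
#' @param x reference image, same shape; must have a positive maximum.
#' @return PSNR in decibels.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(255, 4, 4))  # MSE = xmax^2 -> 0 dB
#' @export
psnr <- function(xhat, x) {
  xhat <- frameStack(xhat); x <- frameStack(x)
  if (!all(dim(xhat) == dim(x))) stop("shape mismatch")
  xmax <- max(x)
  if (xmax <= 0) stop("reference image maximum must be positive")
  m <- mean((xhat - x)^2)
  if (m == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(xmax^2 / m)
}

msssimDefaultWeights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

# dyadic downsampling: 2x2 average pooling, floor sizes
downsample2 <- function(x) {
  nr <- nrow(x) %/% 2L; nc <- ncol(x) %/% 2L
  0.25 * (x[2 * seq_len(nr) - 1L, 2 * seq_len(nc) - 1L, drop = FALSE] +
          x[2 * seq_len(nr), 2 * seq_len(nc) - 1L, drop = FALSE] +
          x[2 * seq_len(nr) - 1L, 2 * seq_len(nc), drop = FALSE] +
          x[2 * seq_len(nr), 2 * seq_len(nc), drop = FALSE])
}

#' Multiscale structural similarity (MS-SSIM)
#'
#' \deqn{\mathrm{MS\!-\!SSIM}(\hat x, x) = [l_M]^{\gamma_M}
#'   \prod_{m=1}^{M} [c_m s_m]^{\gamma_m}}
#' with the luminance term evaluated at the coarsest level only and
#' contrast/structure at every level; images are downsampled dyadically
#' (2x2 average pooling) between levels. Default: 5 levels with the
#' standard exponents (0.0448, 0.2856, 0.3001, 0.2363, 0.1333). Each
#' level's contrast-structure map is averaged and clamped at 0 before
#' exponentiation.
#'
#' Levels must satisfy \code{min(dim) / 2^(levels-1) >= 8}; smaller
#' desk-scale images automatically use fewer levels with the leading
#' weights renormalized to sum to 1, unless \code{levels} is given
#' explicitly, in which case an over-deep request is an error telling the
#' caller to lower \code{levels}.
#'
#' @param xhat,x single-frame images (matrices of equal shape).
#' @param levels number of scales M (default: automatic, at most 5).
#' @param weights exponent vector, one entry per level.
#' @param L intensity dynamic range of the reference (default
#'   \code{max(x)}, falling back to 1 for an all-zero reference).
#' @param window,sigma SSIM window parameters.
#' @return scalar MS-SSIM in (-1, 1]; 1 for identical images.
#' @examples
#' x <- matrix(runif(128 * 128), 128, 128)
#' msSSIM(x, x)  # 1
#' @export
msSSIM <- function(xhat, x, levels = NULL, weights = NULL, L = NULL,
                   window = 11L, sigma = 1.5) {
  if (!all(dim(xhat) == dim(x))) stop("shape mismatch")
  maxLevels <- max(1L, floor(log2(min(dim(x)) / 8)) + 1L)
  if (is.null(levels)) {
    levels <- min(5L, maxLevels)
  } else if (levels > maxLevels) {
    stop(sprintf(
      "image too small for %d levels (min side %d); lower 'levels' to <= %d",
      levels, min(dim(x)), maxLevels))
  }
  if (is.null(weights)) {
    weights <- msssimDefaultWeights[seq_len(levels)]
    weights <- weights / sum(weights)
  }
  if (length(weights) != levels)
    stop("'weights' must have one entry per level")
  if (is.null(L)) {
    L <- max(x)
    if (L <= 0) L <- 1
  }
  val <- 1
  for (m in seq_len(levels)) {
    core <- ssimCore(xhat, x, L, window, sigma)
    if (m < levels) {
      mcs <- max(mean(core$cs), 0)
      val <- val * mcs^weights[m]
      xhat <- downsample2(xhat)
      x <- downsample2(x)
    } else {
      msl <- max(mean(core$S), 0)  # luminance enters at the last level
      val <- val * msl^weights[m]
    }
  }
  val
}

#' Evaluate a reconstructed dynamic image against a reference
#'
#' Computes MSE, MS-SSIM and PSNR frame by frame plus their unweighted
#' means across frames (one summary row labelled "mean"), the layout used
#' for per-tracer quantitative reporting.
#'
#' @param xhat estimated [DynamicImage-class] (or H x W x F array).
#' @param x reference [DynamicImage-class] (or array), same shape.
#' @param tracer optional tracer tag stored in the output.
#' @param reference identifier of the reference convention (e.g. "label"
#'   or "truth").
#' @param ... passed to [msSSIM()] (levels, window, ...).
#' @return data.frame with F + 1 rows and columns tracer, frame, mse,
#'   ms_ssim, psnr.
#' @export
evaluatePair <- function(xhat, x, tracer = NA_character_,
                         reference = "label", ...) {
  a <- frameStack(xhat); b <- frameStack(x)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  nF <- dim(a)[3]
  rows <- lapply(seq_len(nF), function(f) {
    m <- mean((a[, , f] - b[, , f])^2)
    ms <- msSSIM(a[, , f], b[, , f], ...)
    xmax <- max(b[, , f])
    p <- if (m == 0) Inf else if (xmax <= 0) NA_real_
         else 10 * log10(xmax^2 / m)
    data.frame(tracer = tracer, frame = as.character(f), mse = m,
               ms_ssim = ms, psnr = p, reference = reference)
  })
  tab <- do.call(rbind, rows)
  summaryRow <- data.frame(tracer = tracer, frame = "mean",
                           mse = mean(tab$mse), ms_ssim = mean(tab$ms_ssim),
                           psnr = mean(tab$psnr), reference = reference)
  rbind(tab, summaryRow)
}
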