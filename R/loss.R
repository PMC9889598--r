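#' @include nn.R
NULL

# Cached 1-D Gaussian convolution matrices for windowed SSIM statistics.
# blurNorm(X) = (Kr %*% X %*% t(Kc)) / normM with the window renormalized
# at the borders, so local means stay unbiased near the edges.
.blurCache <- new.env(parent = emptyenv())

gaussConvMatrix <- function(n, window, sigma) {
  key <- paste(n, window, sigma, sep = "_")
  if (!is.null(.blurCache[[key]])) return(.blurCache[[key]])
  half <- (window - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- (i - half):(i + half)
    ok <- js >= 1 & js <= n
    K[i, js[ok]] <- g[ok]
  }
  .blurCache[[key]] <- K
  K
}

blurPair <- function(nr, nc, window, sigma) {
  Kr <- gaussConvMatrix(nr, window, sigma)
  Kc <- gaussConvMatrix(nc, window, sigma)
  normM <- rowSums(Kr) %o% rowSums(Kc)
  list(Kr = Kr, Kc = Kc, norm = normM)
}

blurN <- function(X, bp) (bp$Kr %*% X %*% t(bp$Kc)) / bp$norm
blurAdj <- function(U, bp) t(bp$Kr) %*% (U / bp$norm) %*% bp$Kc

# Windowed SSIM statistics of two single-frame images; returns the map
# and the intermediates needed for the analytic gradient.
ssimCore <- function(x, y, L, window, sigma) {
  if (!all(dim(x) == dim(y))) stop("image shapes differ")
  bp <- blurPair(nrow(x), ncol(x), window, sigma)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mx <- blurN(x, bp); my <- blurN(y, bp)
  sxx <- blurN(x * x, bp) - mx^2
  syy <- blurN(y * y, bp) - my^2
  sxy <- blurN(x * y, bp) - mx * my
  A1 <- 2 * mx * my + C1
  A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1
  B2 <- sxx + syy + C2
  list(S = (A1 * A2) / (B1 * B2), lum = A1 / B1, cs = A2 / B2,
       mx = mx, my = my, A1 = A1, A2 = A2, B1 = B1, B2 = B2, bp = bp)
}

#' Single-scale structural similarity (SSIM)
#'
#' Mean SSIM over an 11x11 Gaussian window (sigma 1.5) with stability
#' constants \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}. The window is
#' renormalized at image borders, so images smaller than the window are
#' handled gracefully.
#'
#' @param x,y single-frame images (matrices of equal shape).
#' @param L intensity dynamic range (default 1, the normalized label
#'   scale).
#' @param window window side length (default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @return scalar mean SSIM (1 for identical images).
#' @export
ssim <- function(x, y, L = 1, window = 11L, sigma = 1.5) {
  mean(ssimCore(x, y, L, window, sigma)$S)
}

# Gradient of mean SSIM with respect to x.
ssimGradX <- function(core, x, y) {
  N <- length(x)
  D <- core$B1 * core$B2
  dS_dA1 <- core$A2 / D
  dS_dA2 <- core$A1 / D
  S <- core$S
  dS_dB1 <- -S / core$B1
  dS_dB2 <- -S / core$B2
  dS_dmx <- dS_dA1 * 2 * core$my + dS_dB1 * 2 * core$mx
  P <- (dS_dmx - 2 * core$mx * dS_dB2 - core$my * 2 * dS_dA2) / N
  Q <- dS_dB2 / N
  R <- 2 * dS_dA2 / N
  blurAdj(P, core$bp) + 2 * x * blurAdj(Q, core$bp) +
    y * blurAdj(R, core$bp)
}

#' Loss specification for network training
#'
#' The per-frame training loss is
#' \deqn{L(\hat x, x) = \alpha\, \mathrm{MSE}(\hat x, x)
#'   - \beta \ln \frac{1 + \mathrm{SSIM}(\hat x, x)}{2},}
#' nonnegative whenever SSIM <= 1 and zero iff the frames are identical.
#'
#' @param alpha MSE weight (simulation default 100).
#' @param beta SSIM-term weight (simulation default 1).
#' @param L SSIM intensity dynamic range on the normalized label scale
#'   (default 1).
#' @param window,sigma SSIM window size and Gaussian sigma.
#' @return a list of class "lossSpec".
#' @export
lossSpec <- function(alpha = 100, beta = 1, L = 1, window = 11L,
                     sigma = 1.5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, L = L, window = as.integer(window),
                 sigma = sigma), class = "lossSpec")
}

#' Per-frame training loss
#'
#' @param xhat estimated single-frame image (matrix).
#' @param x label single-frame image (matrix, same shape).
#' @param spec a [lossSpec()].
#' @return scalar loss \eqn{\alpha\,MSE - \beta \ln((1+SSIM)/2)}.
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' lossSingle(x, x, lossSpec())  # 0
#' @export
lossSingle <- function(xhat, x, spec = lossSpec()) {
  if (!all(dim(xhat) == dim(x))) stop("shape mismatch between xhat and x")
  m <- mean((xhat - x)^2)
  s <- ssim(xhat, x, spec$L, spec$window, spec$sigma)
  spec$alpha * m - spec$beta * log((1 + s) / 2)
}

# loss and gradient wrt xhat for one frame
lossSingleGrad <- function(xhat, x, spec) {
  core <- ssimCore(xhat, x, spec$L, spec$window, spec$sigma)
  s <- mean(core$S)
  m <- mean((xhat - x)^2)
  val <- spec$alpha * m - spec$beta * log((1 + s) / 2)
  grad <- spec$alpha * 2 * (xhat - x) / length(x) -
    spec$beta / (1 + s) * ssimGradX(core, xhat, x)
  list(value = val, grad = grad)
}

frameStack <- function(x) {
  if (is(x, "DynamicImage")) x@data else x
}

#' Total multi-task training loss
#'
#' Sum of the per-frame losses of the two tracers, averaged over frames:
#' \deqn{L_{total} = \frac{1}{F} \sum_{f=1}^{F}
#'   L(\hat x^I_f, x^I_f) + L(\hat x^{II}_f, x^{II}_f).}
#'
#' @param xhatI,xI,xhatII,xII dynamic images (H x W x F arrays or
#'   [DynamicImage-class] objects) with equal frame counts.
#' @param spec a [lossSpec()].
#' @return scalar total loss.
#' @export
lossTotal <- function(xhatI, xI, xhatII, xII, spec = lossSpec()) {
  a1 <- frameStack(xhatI); l1 <- frameStack(xI)
  a2 <- frameStack(xhatII); l2 <- frameStack(xII)
  nF <- dim(a1)[3]
  if (dim(l1)[3] != nF || dim(a2)[3] != nF || dim(l2)[3] != nF)
    stop("frame counts differ between inputs")
  tot <- 0
  for (f in seq_len(nF))
    tot <- tot + lossSingle(a1[, , f], l1[, , f], spec) +
      lossSingle(a2[, , f], l2[, , f], spec)
  tot / nF
}

# value + per-branch gradients (H x W x F arrays), for training
lossTotalGrad <- function(xhatI, xI, xhatII, xII, spec) {
  nF <- dim(xhatI)[3]
  g1 <- array(0, dim(xhatI)); g2 <- array(0, dim(xhatII))
  tot <- 0
  for (f in seq_len(nF)) {
    r1 <- lossSingleGrad(xhatI[, , f], xI[, , f], spec)
    r2 <- lossSingleGrad(xhatII[, , f], xII[, , f], spec)
    tot <- tot + r1$value + r2$value
    g1[, , f] <- r1$grad / nF
    g2[, , f] <- r2$grad / nF
  }
  list(value = tot / nF, gradI = g1, gradII = g2)
}
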