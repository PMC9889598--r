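test_that("the combined MSE/SSIM loss vanishes only for perfect frames", {
  set.seed(21)
  x <- matrix(runif(64), 8, 8)
  spec <- lossSpec()
  expect_equal(lossSingle(x, x, spec), 0)

  y <- x + matrix(rnorm(64, sd = 0.05), 8, 8)
  expect_gt(lossSingle(y, x, spec), 0)
  # decomposes exactly into its MSE and SSIM parts
  expect_equal(lossSingle(y, x, spec),
               spec$alpha * mse(y, x) -
                 spec$beta * log((1 + ssim(y, x)) / 2),
               tolerance = 1e-12)
  expect_error(lossSingle(matrix(0, 4, 4), x, spec), "mismatch")
})

test_that("total loss averages the two tracers' frame losses", {
  set.seed(22)
  spec <- lossSpec(alpha = 100, beta = 1)
  mk <- function() array(runif(16 * 16 * 3), c(16, 16, 3))
  xh1 <- mk(); x1 <- mk(); xh2 <- mk(); x2 <- mk()

  expect_equal(lossTotal(x1, x1, x2, x2, spec), 0)

  # explicit per-frame loop oracle
  loop <- 0
  for (f in 1:3)
    loop <- loop + lossSingle(xh1[, , f], x1[, , f], spec) +
      lossSingle(xh2[, , f], x2[, , f], spec)
  expect_equal(lossTotal(xh1, x1, xh2, x2, spec), loop / 3,
               tolerance = 1e-10)

  # F = 1 reduces to the sum of two single-frame losses
  one <- function(a) a[, , 1, drop = FALSE]
  expect_equal(lossTotal(one(xh1), one(x1), one(xh2), one(x2), spec),
               lossSingle(xh1[, , 1], x1[, , 1], spec) +
                 lossSingle(xh2[, , 1], x2[, , 1], spec),
               tolerance = 1e-12)

  expect_error(lossTotal(xh1, x1, xh2, x2[, , 1:2], spec), "frame")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(23)
  spec <- lossSpec(alpha = 100, beta = 1)
  xh <- array(runif(8 * 8), c(8, 8, 1))
  x <- array(runif(8 * 8), c(8, 8, 1))
  lg <- dualtracer:::lossTotalGrad(xh, x, xh * 0.5, x, spec)
  eps <- 1e-6
  worst <- 0
  for (i in c(1, 9, 33, 64)) {
    xp <- xh; xp[i] <- xp[i] + eps
    fd <- (lossTotal(xp, x, xh * 0.5, x, spec) -
             lossTotal(xh, x, xh * 0.5, x, spec)) / eps
    worst <- max(worst, abs(fd - lg$gradI[i]) / max(abs(fd), 1e-8))
  }
  expect_lt(worst, 1e-4)
})
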