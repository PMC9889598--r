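test_that("MSE matches an explicit double-loop computation", {
  set.seed(31)
  a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(matrix(2, 3, 3), matrix(0, 3, 3)), 4)
  acc <- 0
  for (i in 1:5) for (j in 1:5) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(mse(a, b), acc / 25, tolerance = 1e-12)
  expect_error(mse(a, matrix(0, 3, 3)), "mismatch")
})

test_that("PSNR follows its closed form and scale invariance", {
  ref <- matrix(255, 4, 4)
  expect_equal(psnr(matrix(0, 4, 4), ref), 0)        # MSE = xmax^2
  off <- ref - 1                                      # MSE = 1, xmax = 255
  expect_equal(psnr(off, ref), 10 * log10(65025), tolerance = 1e-10)
  expect_equal(psnr(off, ref), 48.1308, tolerance = 1e-4)

  set.seed(32)
  a <- matrix(runif(64, 0.1, 1), 8, 8); b <- matrix(runif(64, 0.1, 1), 8, 8)
  expect_equal(psnr(3 * a, 3 * b), psnr(a, b), tolerance = 1e-10)

  expect_warning(p <- psnr(a, a), "infinite")
  expect_identical(p, Inf)
  expect_error(psnr(a, matrix(0, 8, 8)), "positive")

  # strictly decreasing in MSE for a fixed reference
  p1 <- psnr(b + 0.01, b); p2 <- psnr(b + 0.02, b)
  expect_gt(p1, p2)
})

test_that("MS-SSIM matches the independent reference implementation", {
  pair <- fixtureImagePair(128)
  # values frozen from an independent NumPy/SciPy implementation of the
  # same windowing conventions
  expect_equal(msSSIM(pair$xhat, pair$x, levels = 5, L = 1),
               0.986971611228, tolerance = 1e-6)
  expect_equal(msSSIM(pair$xhat, pair$x, levels = 3, L = 1),
               0.982112660339, tolerance = 1e-6)
  expect_equal(ssim(pair$xhat, pair$x, L = 1),
               0.861220209825, tolerance = 1e-6)
  expect_equal(msSSIM(pair$xhat[1:32, 1:32], pair$x[1:32, 1:32],
                      levels = 3, L = 1),
               0.982395834576, tolerance = 1e-6)
})

test_that("MS-SSIM identities, symmetry and level handling", {
  pair <- fixtureImagePair(64)
  x <- pair$x; y <- pair$xhat
  expect_equal(msSSIM(x, x), 1)
  expect_equal(msSSIM(x, x, levels = 1, weights = 1), 1)
  # one level with unit weight reduces to single-scale SSIM
  expect_equal(msSSIM(y, x, levels = 1, weights = 1, L = 1),
               ssim(y, x, L = 1), tolerance = 1e-12)
  # symmetric when the dynamic range is held fixed
  expect_equal(msSSIM(y, x, L = 1), msSSIM(x, y, L = 1), tolerance = 1e-12)
  # too many levels for a small image is a guided error
  expect_error(msSSIM(y[1:16, 1:16], x[1:16, 1:16], levels = 5),
               "lower 'levels'")
  # automatic level reduction handles desk-scale images
  expect_equal(msSSIM(x[1:32, 1:32], x[1:32, 1:32]), 1)
})

test_that("evaluatePair reports per-frame rows plus a summary row", {
  set.seed(33)
  arr <- array(runif(32 * 32 * 2, 0.2, 1), c(32, 32, 2))
  prot <- scanProtocol(c(60, 60))
  img <- new("DynamicImage", data = arr, protocol = prot, tracer = "t")
  self <- evaluatePair(img, img)
  expect_equal(nrow(self), 3L)              # F + 1 rows
  expect_equal(self$mse[1:2], c(0, 0))
  expect_equal(self$ms_ssim[1:2], c(1, 1))

  noisy <- img
  noisy@data <- pmin(pmax(arr + array(rnorm(length(arr), sd = 0.05),
                                      dim(arr)), 0), 2)
  ev <- evaluatePair(noisy, img)
  perFrame <- ev[ev$frame != "mean", ]
  for (col in c("mse", "ms_ssim", "psnr"))
    expect_equal(ev[ev$frame == "mean", col], mean(perFrame[[col]]),
                 tolerance = 1e-12)
})
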