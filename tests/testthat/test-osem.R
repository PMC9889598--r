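test_that("OSEM leaves the true image fixed on consistent data", {
  sm <- cachedSysmat(32, 40)
  ph <- makePhantom(2, size = 32, seed = 5)
  truth <- matrix(0.5, 32, 32); truth[labelMap(ph) > 0] <- 2  # strictly > 0
  img <- new("DynamicImage", data = array(truth, c(32, 32, 1)),
             protocol = scanProtocol(60), tracer = "t")
  y <- forwardProject(img, sm)
  rec <- osem(y, sm, nIter = 1, nSubsets = 5, init = truth)
  expect_lt(max(abs(rec@data[, , 1] - truth) / truth), 1e-10)
})

test_that("EM converges on noiseless data and stays nonnegative", {
  sm <- cachedSysmat(32, 40)
  img <- diskImage(32, 10, value = 3)
  y <- forwardProject(img, sm)
  rec <- osem(y, sm, nIter = 200, nSubsets = 1)
  resid <- forwardProject(rec, sm)
  relres <- sqrt(sum((resid@data - y@data)^2)) / sqrt(sum(y@data^2))
  expect_lt(relres, 0.01)
  expect_true(all(rec@data >= 0))
})

test_that("MLEM monotonically increases the Poisson log-likelihood", {
  sm <- cachedSysmat(16, 10)
  img <- diskImage(16, 5, value = 4)
  clean <- forwardProject(img, sm)
  y <- addNoise(clean, countLevel = 5e4, randomsFraction = 0, seed = 3)
  lls <- vapply(1:12, function(k) {
    rec <- osem(y, sm, nIter = k, nSubsets = 1)
    poissonLogLik(y, rec, sm)
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-6 * abs(lls[-1])))
})

test_that("OSEM guards degenerate inputs", {
  sm <- cachedSysmat(16, 10)
  zero <- new("DynamicSinogram",
              data = array(0, c(16, 10, 1)),
              geometry = geometry(sm), protocol = scanProtocol(60))
  expect_warning(rec <- osem(zero, sm), "all-zero")
  expect_equal(sum(rec@data), 0)

  noisy <- addNoise(forwardProject(diskImage(16, 5), sm), 1e4, 0.2, seed = 1)
  rec <- osem(noisy, sm, nIter = 6, nSubsets = 5)
  expect_true(all(is.finite(rec@data)))
  expect_true(all(rec@data >= 0))
  expect_error(osem(noisy, sm, nSubsets = 11), "subsets")
})

test_that("split-half baseline halves the input and conserves activity", {
  img <- diskImage(32, 9, value = 4)
  halves <- splitHalfBaseline(img)
  expect_equal(dataArray(halves$I), dataArray(img) / 2)
  expect_equal(dataArray(halves$I) + dataArray(halves$II), dataArray(img))
})
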