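test_that("default geometry matches the target sinogram shape", {
  g <- systemGeometry()
  expect_equal(g@nBins, 128L)
  expect_equal(g@nAngles, 160L)
  expect_error(systemGeometry(0, 160), "nBins")
})

test_that("system matrix is deterministic and sees every pixel", {
  sm1 <- buildSystemMatrix(deskGeometry(16, 10))
  sm2 <- buildSystemMatrix(deskGeometry(16, 10))
  expect_identical(sm1@G, sm2@G)
  expect_true(all(sm1@G@x >= 0))
  expect_true(all(Matrix::colSums(sm1@G) > 0))
})

test_that("a centered pixel at angle 0 hits only the central bins", {
  n <- 17L  # odd: one pixel exactly at the center
  geom <- systemGeometry(17L, 8L, c(n, n), pixelSizeMM = 2,
                         binWidthMM = 2)
  sm <- buildSystemMatrix(geom)
  img <- matrix(0, n, n); img[9, 9] <- 1
  di <- new("DynamicImage", data = array(img, c(n, n, 1)),
            protocol = scanProtocol(60), tracer = "pt")
  sino <- forwardProject(di, sm)
  prof <- sino@data[, 1, 1]  # angle 0
  expect_gt(prof[9], 0)
  expect_equal(sum(prof[-9] > 1e-12), 0L)
})

test_that("strip integrals reproduce the disk chord length at all angles", {
  sm <- cachedSysmat(64, 160)
  geom <- geometry(sm)
  rPx <- 24
  rMM <- rPx * geom@pixelSizeMM
  sino <- forwardProject(diskImage(64, rPx), sm)
  s0 <- -0.5 * (geom@nBins - 1) * geom@binWidthMM
  for (bin in c(32L, 33L)) {  # the two bins straddling s = 0
    s <- s0 + (bin - 1) * geom@binWidthMM
    chord <- 2 * sqrt(rMM^2 - s^2)
    expect_lt(max(abs(sino@data[bin, , 1] - chord)) / chord, 0.02)
  }
})

test_that("forward projection is linear and adjoint-consistent", {
  sm <- cachedSysmat(32, 40)
  prot <- scanProtocol(60)
  mk <- function(m) new("DynamicImage", data = array(m, c(32, 32, 1)),
                        protocol = prot, tracer = "t")
  set.seed(5)
  a <- matrix(abs(rnorm(1024)), 32); b <- matrix(abs(rnorm(1024)), 32)
  zero <- forwardProject(mk(matrix(0, 32, 32)), sm)
  expect_equal(sum(zero@data), 0)
  lin <- forwardProject(mk(2 * a + 3 * b), sm)
  expect_equal(lin@data,
               2 * forwardProject(mk(a), sm)@data +
                 3 * forwardProject(mk(b), sm)@data,
               tolerance = 1e-12)

  x <- rnorm(ncol(sm@G)); y <- rnorm(nrow(sm@G))
  lhs <- sum(as.numeric(sm@G %*% x) * y)
  rhs <- sum(x * as.numeric(Matrix::crossprod(sm@G, y)))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("per-angle mass equals the pixel-weighted image sum", {
  sm <- cachedSysmat(32, 40)
  geom <- geometry(sm)
  img <- diskImage(32, 10)
  sino <- forwardProject(img, sm)
  perAngle <- colSums(matrix(sino@data[, , 1], geom@nBins, geom@nAngles))
  expected <- sum(img@data) * geom@pixelSizeMM^2 / geom@binWidthMM
  expect_lt(max(abs(perAngle - expected)) / expected, 0.02)
})

test_that("noise model respects the count level and randoms fraction", {
  sm <- cachedSysmat(32, 40)
  img <- diskImage(32, 10, value = 5)
  clean <- forwardProject(img, sm)

  zero <- clean; zero@data[] <- 0
  out0 <- addNoise(zero, countLevel = 1e5, randomsFraction = 0, seed = 1)
  expect_equal(sum(out0@data), 0)

  # pure-randoms frame: expected total = countLevel * randomsFraction
  outR <- addNoise(zero, countLevel = 1e6, randomsFraction = 0.2, seed = 2)
  expect_lt(abs(sum(outR@data) - 2e5) / 2e5, 0.05)

  # Poisson relative sd ~ 1/sqrt(N): totals concentrate at countLevel
  # (on the count scale; the returned data are on the intensity scale)
  sc <- 1e7 / sum(clean@data)
  for (s in 1:5) {
    noisy <- addNoise(clean, countLevel = 1e7, randomsFraction = 0, seed = s)
    expect_lt(abs(sum(noisy@data) * sc - 1e7) / 1e7, 0.01)
  }

  # with a 20% randoms background (not subtracted), the returned
  # intensity total inflates by 1 / (1 - rf)
  tot <- sum(clean@data)
  m <- mean(vapply(1:10, function(s)
    sum(addNoise(clean, 1e6, 0.2, seed = s)@data), numeric(1)))
  expect_lt(abs(m - tot / 0.8) / (tot / 0.8), 0.02)

  expect_error(addNoise(clean, countLevel = -1), "positive")
  expect_error(addNoise(clean, countLevel = 1e5, randomsFraction = 1),
               "randomsFraction")
})

test_that("dual-tracer combination is an element-wise Poisson-mean sum", {
  sm <- cachedSysmat(32, 40)
  imgA <- diskImage(32, 10, value = 2)
  imgB <- diskImage(32, 6, value = 4)
  A <- forwardProject(imgA, sm); B <- forwardProject(imgB, sm)

  zero <- A; zero@data[] <- 0
  expect_equal(combineTracers(A, zero)@data, A@data)
  expect_equal(combineTracers(A, B)@data, combineTracers(B, A)@data)

  other <- new("DynamicSinogram", data = A@data,
               geometry = A@geometry, protocol = scanProtocol(30))
  expect_error(combineTracers(A, other), "protocol")

  # sums of independent Poisson samples have mean mu1 + mu2
  nrep <- 200
  tots <- vapply(seq_len(nrep), function(s) {
    nA <- addNoise(A, 1e4, 0, seed = s)
    nB <- addNoise(B, 1e4, 0, seed = 1e6 + s)
    sum(combineTracers(nA, nB)@data)
  }, numeric(1))
  muA <- sum(A@data); muB <- sum(B@data)
  # totals are rescaled to intensity units; expectation is muA + muB
  se <- sd(tots) / sqrt(nrep)
  expect_lt(abs(mean(tots) - (muA + muB)), 3 * se + 1e-9)
})
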