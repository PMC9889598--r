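test_that("plasma input functions are bolus-shaped and validated", {
  tr <- defaultTracer("FDG")
  t <- seq(0, 3600, by = 1)
  cp <- inputFunction(t, tr)
  expect_equal(cp[1], 0)            # C_P(0) = 0
  expect_true(all(cp >= 0))
  expect_lt(cp[length(cp)], max(cp) / 4)   # decays well below the peak

  zero <- tracerSpec("null", 1000, "feng", rep(0, 6))
  expect_equal(inputFunction(t, zero), rep(0, length(t)))

  # independent re-evaluation of the closed form at t = 600 s
  p <- tr@inputParams
  tm <- 10
  expected <- (p[1] * tm - p[2] - p[3]) * exp(-p[4] * tm) +
    p[2] * exp(-p[5] * tm) + p[3] * exp(-p[6] * tm)
  expect_equal(inputFunction(600, tr), expected, tolerance = 1e-12)

  bad <- tracerSpec("bad", 1000, "mystery", 1)
  expect_error(inputFunction(t, bad), "unknown input model")
  expect_error(inputFunction(-1, tr), "nonnegative")
})

test_that("Gaussian parameter randomization matches the requested cv", {
  means <- defaultKinetics("FDG", 3)
  exact <- sampleParameters(means, cv = 0, nSets = 3, seed = 1)
  for (s in exact) expect_equal(s, means)

  draws <- sampleParameters(1, cv = 0.10, nSets = 1e4, seed = 42)
  v <- unlist(draws)
  expect_gt(sd(v) / mean(v), 0.09)
  expect_lt(sd(v) / mean(v), 0.11)

  big <- unlist(sampleParameters(0.05, cv = 0.20, nSets = 1e5, seed = 7))
  expect_true(all(big > 0))       # redraw policy leaves no mass at 0

  expect_error(sampleParameters(means, cv = 1, nSets = 1), "cv")
  # zero means stay exactly zero
  z <- sampleParameters(c(0, 0.1), cv = 0.2, nSets = 5, seed = 1)
  expect_true(all(vapply(z, function(s) s[1] == 0, logical(1))))
})

test_that("compartment solver reproduces closed forms and the ODE oracle", {
  t <- seq(0, 1800, by = 1)
  expect_equal(solve2TCM(c(0, 0, 0, 0), rep(1, length(t)), t)@values,
               rep(0, length(t)))

  # one-tissue model, unit-step input: C_T(t) = 1 - exp(-k2 t)
  ct <- solve2TCM(c(0.1, 0.1, 0, 0), rep(1, length(t)), t)
  expect_equal(ct@values[601], 1 - exp(-1), tolerance = 1e-6)

  cp <- inputFunction(t, defaultTracer("FDG"))
  cpFun <- approxfun(t / 60, cp, rule = 2)
  set.seed(123)
  worst <- 0
  for (i in 1:20) {
    p <- c(runif(1, 0.05, 0.9), runif(1, 0.05, 1.2),
           runif(1, 0, 0.4), runif(1, 0, 0.06))
    mine <- solve2TCM(p, cp, t)@values
    oracle <- ode2TCMOracle(p, cpFun, t)
    worst <- max(worst, max(abs(mine - oracle)) / max(oracle))
  }
  expect_lt(worst, 1e-3)

  expect_error(solve2TCM(c(-0.1, 0.1, 0, 0), cp, t), "nonnegative")
})

test_that("tissue response is linear in the plasma input", {
  t <- seq(0, 1200, by = 1)
  cp <- inputFunction(t, defaultTracer("FMZ"))
  p <- c(0.3, 0.4, 0.06, 0.04)
  one <- solve2TCM(p, cp, t)@values
  three <- solve2TCM(p, 3 * cp, t)@values
  expect_equal(three, 3 * one, tolerance = 1e-12)
})

test_that("frame averaging is exact for linear TACs", {
  prot <- parseProtocol("30s×4+110s×12+180s×2")
  t <- seq(0, 1800, by = 1)
  lin <- new("TAC", time = t, values = 2 * t + 5)
  expect_equal(frameAverage(lin, prot), 2 * midFrameTimes(prot) + 5)
})

test_that("dynamic images have the right shape, support and ROI structure", {
  ph <- makePhantom(3, size = 32, seed = 7)
  prot <- parseProtocol("30s×4+110s×12+180s×2")
  img <- makeDynamicImage(ph, defaultKinetics("FMZ", 3),
                          defaultTracer("FMZ"), prot)
  expect_equal(dim(dataArray(img)), c(32L, 32L, 18L))
  arr <- dataArray(img)
  expect_true(all(arr >= 0))
  expect_true(all(arr[, , 5][labelMap(ph) == 0] == 0))  # background = 0
  # piecewise-constant per ROI in every frame
  for (f in c(1, 9, 18)) {
    frame <- arr[, , f]
    for (r in 1:3)
      expect_equal(length(unique(frame[labelMap(ph) == r])), 1L)
  }
  expect_error(
    makeDynamicImage(ph, defaultKinetics("FMZ", 2), defaultTracer("FMZ"),
                     prot),
    "ROIs")
})

test_that("decay weighting attenuates late frames of short-lived tracers", {
  ph <- makePhantom(2, size = 32, seed = 9)
  prot <- deskProtocol()
  kin <- defaultKinetics("FMZ", 2)
  with_decay <- makeDynamicImage(ph, kin, defaultTracer("FMZ"), prot,
                                 decay = TRUE)
  without <- makeDynamicImage(ph, kin, defaultTracer("FMZ"), prot,
                              decay = FALSE)
  f <- nFrames(prot)
  roi <- labelMap(ph) == 1
  expect_lt(mean(dataArray(with_decay)[, , f][roi]),
            mean(dataArray(without)[, , f][roi]))
})
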