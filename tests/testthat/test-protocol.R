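test_that("protocol strings expand to the right frames and durations", {
  p <- parseProtocol("30s×4+110s×12+180s×2")
  expect_equal(nFrames(p), 18L)
  expect_equal(totalDuration(p), 1800)
  expect_equal(frameDurations(p), c(rep(30, 4), rep(110, 12), rep(180, 2)))

  p1 <- parseProtocol("60s×1")
  expect_equal(nFrames(p1), 1L)
  expect_equal(midFrameTimes(p1), 30)

  expect_equal(totalDuration(parseProtocol("60s×2+90s×2+150s×14")), 2400)
  # plain ASCII 'x' is accepted as the separator
  expect_equal(nFrames(parseProtocol("30s x 4 + 110sx12+180sx2")), 18L)
})

test_that("mid-frame times are frame starts plus half durations", {
  p <- parseProtocol("30s×2+60s×2")
  fe <- frameEdges(p)
  expect_equal(unname(fe[, "start"]), c(0, 30, 60, 120))
  expect_equal(unname(fe[, "end"]), c(30, 60, 120, 180))
  expect_equal(midFrameTimes(p), c(15, 45, 90, 150))
  expect_true(all(diff(midFrameTimes(p)) > 0))
})

test_that("malformed protocol terms and degenerate protocols are rejected", {
  expect_error(parseProtocol("30×4"), "malformed")
  expect_error(parseProtocol("30s×"), "malformed")
  expect_error(parseProtocol(""), "empty|malformed")
  expect_error(scanProtocol(c(30, -1)), "positive")
  expect_error(scanProtocol(numeric(0)), "at least one")
})
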