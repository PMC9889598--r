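test_that("phantom generation is deterministic and partitions the grid", {
  a <- makePhantom(3, size = 128, seed = 7)
  b <- makePhantom(3, size = 128, seed = 7)
  expect_identical(labelMap(a), labelMap(b))

  ph <- makePhantom(2, size = 128, seed = 1)
  counts <- table(labelMap(ph))
  expect_identical(sort(as.integer(names(counts))), 0:2)
  expect_true(all(counts > 0))
  expect_equal(sum(counts), 128L * 128L)
})

test_that("every ROI stays nonempty even when small and crowded", {
  ph <- makePhantom(5, size = 32, seed = 3)
  counts <- tabulate(as.integer(labelMap(ph)) + 1L, nbins = 6L)
  expect_true(all(counts[-1] >= 4))
  expect_equal(sum(counts), 32L * 32L)
})

test_that("phantom ROI counts are validated", {
  expect_error(makePhantom(1, size = 64), "between 2 and 5")
  expect_error(makePhantom(6, size = 64), "between 2 and 5")
  expect_error(makePhantom(3, size = 8), "size")
})

test_that("phantom libraries cycle ROI counts and reproduce per seed", {
  lib <- makePhantomLibrary(8, size = 64, seed = 2)
  expect_length(lib, 8L)
  expect_setequal(vapply(lib, nROIs, integer(1)), 2:5)

  expect_length(makePhantomLibrary(1, size = 64, seed = 0), 1L)

  lib2 <- makePhantomLibrary(8, size = 64, seed = 2)
  expect_identical(lapply(lib, labelMap), lapply(lib2, labelMap))
})

test_that("phantoms survive a NIfTI + YAML round trip", {
  ph <- makePhantom(4, size = 32, seed = 11)
  path <- file.path(withr::local_tempdir(), "ph.nii")
  writePhantom(ph, path)
  back <- readPhantom(path)
  expect_identical(labelMap(back), labelMap(ph))
  expect_equal(nROIs(back), nROIs(ph))
  expect_equal(back@pixelSizeMM, ph@pixelSizeMM)
})
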