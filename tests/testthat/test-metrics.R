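test_that("autofluorescence removal respects its bounds", {
  px <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32) * 1.0
  img <- SectionImage(px)
  expect_true(all(pixels(removeAutofluorescence(img, max(px))) == 0))
  expect_identical(pixels(removeAutofluorescence(img, min(px) - 1)), px)
  ## strictly-greater convention: pixels at the threshold are background
  at <- removeAutofluorescence(img, px[1, 1])
  expect_identical(unname(pixels(at)[1, 1]), 0)
})

test_that("masking, AROSA and MPD match brute-force pixel scans", {
  set.seed(99)
  for (i in 1:10) {
    px <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64) * 1.0
    thr <- runif(1, 20, 230)
    surf <- sample(5:20, 64, TRUE)
    img <- SectionImage(px)
    masked <- removeAutofluorescence(img, thr)
    expect_identical(pixels(masked), bfMask(px, thr))
    expect_equal(computeArosa(masked), bfArosa(pixels(masked)))
    mp <- computeMpd(masked, surf)
    expect_equal(mp$mpdUm, bfMpd(pixels(masked), surf, pixelScale(img)))
  }
})

test_that("AROSA arithmetic: retained sum over total pixel count", {
  px <- matrix(0, 100, 100)
  px[sample.int(10000, 500)] <- 200
  img <- SectionImage(px)
  expect_equal(computeArosa(img), 500 * 200 / 10000)   # = 10
  expect_equal(computeArosa(img, perRetainedPixel = TRUE), 200)
  expect_equal(computeArosa(SectionImage(matrix(0, 10, 10))), 0)
})

test_that("MPD arithmetic and degenerate cases", {
  px <- matrix(0, 60, 3)
  px[15, 2] <- 90    # 10 px below surface row 5
  px[35, 2] <- 90    # 30 px below
  img <- SectionImage(px, scaleUmPerPx = 2.84)
  mp <- computeMpd(img, rep(5L, 3))
  expect_equal(mp$mpdUm, 20 * 2.84)                    # = 56.8 um
  expect_identical(mp$nSignalPx, 2L)

  empty <- computeMpd(SectionImage(matrix(0, 8, 8)), rep(2L, 8))
  expect_equal(empty$mpdUm, 0)
  expect_identical(empty$flags, "NO_SIGNAL")

  ## pixels above the surface are excluded from the depth average
  above <- matrix(0, 20, 2)
  above[2, 1] <- 50        # above surface row 10
  above[14, 1] <- 50       # 4 px below
  mpa <- computeMpd(SectionImage(above, scaleUmPerPx = 1), rep(10L, 2))
  expect_equal(mpa$mpdUm, 4)
  expect_identical(mpa$nSignalPx, 2L)
  expect_identical(mpa$nDepthPx, 1L)

  ## signal in a column with no surface is skipped and flagged
  nosurf <- matrix(0, 20, 2)
  nosurf[12, 2] <- 80
  mps <- computeMpd(SectionImage(nosurf), c(4L, NA))
  expect_equal(mps$mpdUm, 0)
  expect_match(mps$flags[1], "MISSING_SURFACE_COLUMNS:1")
})

test_that("per-image metrics object enforces the NO_SIGNAL invariant", {
  expect_error(new("PenetrationMetrics", thresholdValue = 10, method = "x",
                   arosaMgvPerPx = 5, mpdUm = 1, nSignalPx = 0L,
                   flags = "NO_SIGNAL"),
               "arosa == 0")
  ok <- new("PenetrationMetrics", thresholdValue = 10, method = "x",
            arosaMgvPerPx = 0, mpdUm = 0, nSignalPx = 0L,
            flags = "NO_SIGNAL")
  expect_identical(arosa(ok), 0)
  expect_identical(mpdUm(ok), 0)
})
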