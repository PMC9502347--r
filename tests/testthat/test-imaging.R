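test_that("channel extraction passes grayscale through and splits RGB", {
  m <- matrix(1:12, 3, 4) * 1.0
  img <- extractChannel(m, "gray")
  expect_identical(pixels(img), m)

  arr <- array(0, c(3, 4, 3))
  arr[, , 2] <- m
  green <- extractChannel(arr, "hydrophilic")
  expect_identical(pixels(green), m)
  red <- extractChannel(arr, "lipophilic")
  expect_true(all(pixels(red) == 0))
  expect_error(extractChannel(m, "hydrophilic"), "absent")
})

test_that("metrics on an extracted RGB channel equal the grayscale render", {
  p <- quickParams(dyeAmount = 100)
  r <- generateSectionImage(p, seed = 4)
  arr <- renderRGB(r$image, "lipophilic")
  chan <- extractChannel(arr, "lipophilic", scaleUmPerPx = pixelScale(r$image))
  expect_identical(pixels(chan), pixels(r$image))
  thr <- 70
  mGray <- measureImage(r$image, thr)
  mChan <- measureImage(chan, thr)
  expect_equal(mChan$row$arosa, mGray$row$arosa)
  expect_equal(mChan$row$mpd_um, mGray$row$mpd_um)
  expect_equal(mChan$row$sct_um, mGray$row$sct_um)
})

test_that("a flat noise-free surface is recovered exactly in every column", {
  p <- quickParams(surfaceRowMeanPx = 25, surfaceRoughnessPx = 0,
                   noiseSd = 0, dyeAmount = 0)
  r <- generateSectionImage(p, seed = 1)
  sf <- detectSurface(r$image)
  expect_true(all(sf == 25L))
})

test_that("an all-zero image raises SURFACE_NOT_FOUND", {
  img <- SectionImage(matrix(0, 64, 32))
  expect_error(detectSurface(img), class = "dermaquant_surface_not_found")
})

test_that("surface recovery is sub-pixel on noisy renders", {
  errs <- vapply(seq_len(200), function(i) {
    p <- quickParams(surfaceRoughnessPx = 1, dyeAmount = 0)
    r <- generateSectionImage(p, seed = 3000 + i)
    sf <- detectSurface(r$image)
    mean(abs(sf - trueSurfaceRows(r$truth)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(errs), 1)
})

test_that("SCT and AF-SC are exact on a noise-free synthetic band", {
  ## hand-built image: surface at row 31, SC band 20 px of grey 180 over
  ## tissue of grey 60
  px <- matrix(0, 120, 40)
  px[31:50, ] <- 180
  px[51:120, ] <- 60
  img <- SectionImage(px, scaleUmPerPx = 2.84)
  sf <- detectSurface(img)
  expect_true(all(sf == 31L))
  prof <- measureSct(img, sf)
  expect_equal(sctUm(prof), 20 * 2.84)   # 56.8 um
  expect_equal(sctUmSd(prof), 0)
  expect_equal(afSc(prof), 180)
})

test_that("measureSct refuses when too few columns have a surface", {
  px <- matrix(0, 64, 30)
  px[20:64, 1:4] <- 100
  img <- SectionImage(px)
  sf <- suppressWarnings(detectSurface(img))
  expect_error(measureSct(img, sf, nLines = 10), "4 columns")
})

test_that("SCT recovery error is below one pixel on low-noise renders", {
  set.seed(42)
  errs <- vapply(seq_len(15), function(i) {
    s <- runif(1, 10, 40)
    p <- quickParams(sctUm = s, dyeAmount = 0, noiseSd = 1)
    r <- generateSectionImage(p, seed = 4000 + i)
    prof <- measureSct(r$image, detectSurface(r$image))
    abs(sctUm(prof) - trueValues(r$truth)[["sctEffUm"]])
  }, numeric(1))
  expect_lt(mean(errs), 2.84)
})

test_that("scale equivariance: doubling the scale doubles um metrics only", {
  p1 <- quickParams(dyeAmount = 100, scaleUmPerPx = 2.84)
  ## same pixel geometry at doubled physical scale: halve the um inputs' px
  ## equivalents by doubling sctUm and dyeDecayUm
  p2 <- quickParams(dyeAmount = 100, scaleUmPerPx = 5.68, sctUm = 40,
                    dyeDecayUm = 80)
  r1 <- generateSectionImage(p1, seed = 6)
  r2 <- generateSectionImage(p2, seed = 6)
  expect_identical(pixels(r1$image), pixels(r2$image))   # same px grid
  thr <- 70
  m1 <- measureImage(r1$image, thr)
  m2 <- measureImage(r2$image, thr)
  expect_equal(m2$row$sct_um, 2 * m1$row$sct_um)
  expect_equal(m2$row$mpd_um, 2 * m1$row$mpd_um)
  expect_equal(m2$row$arosa, m1$row$arosa)
})
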