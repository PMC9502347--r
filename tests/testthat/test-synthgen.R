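test_that("rendering is bit-exact reproducible for a fixed seed", {
  p <- quickParams()
  r1 <- generateSectionImage(p, seed = 11)
  r2 <- generateSectionImage(p, seed = 11)
  expect_identical(pixels(r1$image), pixels(r2$image))
  expect_identical(trueSurfaceRows(r1$truth), trueSurfaceRows(r2$truth))
  r3 <- generateSectionImage(p, seed = 12)
  expect_false(identical(pixels(r1$image), pixels(r3$image)))
})

test_that("a dye-free noise-free render has no signal below the SC", {
  p <- quickParams(dyeAmount = 0, noiseSd = 0, surfaceRoughnessPx = 0)
  r <- generateSectionImage(p, seed = 1)
  px <- pixels(r$image)
  eff <- trueValues(r$truth)
  surf <- trueSurfaceRows(r$truth)
  below <- matrix(seq_len(nrow(px)), nrow(px), ncol(px)) -
    matrix(surf, nrow(px), ncol(px), byrow = TRUE) >= eff[["sctPx"]]
  expect_true(all(px[below] <= eff[["afTissueLevel"]]))
  ## and the SC band sits at the effective AF level
  band <- !below & sweep(matrix(seq_len(nrow(px)), nrow(px), ncol(px)), 2,
                         surf, ">=")
  expect_true(all(px[band] == round(eff[["afScEff"]])))
})

test_that("SC band thickness follows sctUm / scale", {
  ## 56.8 um at 2.84 um/px and neutral hydration = 20 px
  p <- quickParams(sctUm = 56.8, hydrationIndex = 0.5)
  r <- generateSectionImage(p, seed = 3)
  expect_identical(unname(trueValues(r$truth)[["sctPx"]]), 20)
})

test_that("invalid generator parameters are rejected", {
  expect_error(GeneratorParams(imageHeightPx = 0), "dimensions")
  expect_error(GeneratorParams(sctUm = -1), "sctUm")
  expect_error(GeneratorParams(sctUm = 2000), "image depth")
  expect_error(GeneratorParams(afScLevel = 20, afTissueLevel = 30),
               "brighter")
  expect_error(GeneratorParams(hydrationIndex = 1.5), "hydration")
  expect_error(GeneratorParams(bitDepth = 12), "bitDepth")
})

test_that("hydration coupling is monotone: hydrated SC is thicker and dimmer", {
  pDry <- quickParams(hydrationIndex = 0, noiseSd = 0)
  pWet <- quickParams(hydrationIndex = 1, noiseSd = 0)
  eDry <- effectiveParams(pDry)
  eWet <- effectiveParams(pWet)
  expect_lt(eWet[["afScEff"]], eDry[["afScEff"]])
  expect_gt(eWet[["sctEffUm"]], eDry[["sctEffUm"]])
  ## monotone over a grid, not just at the extremes
  h <- seq(0, 1, by = 0.25)
  af <- vapply(h, function(x)
    effectiveParams(quickParams(hydrationIndex = x))[["afScEff"]],
    numeric(1))
  sct <- vapply(h, function(x)
    effectiveParams(quickParams(hydrationIndex = x))[["sctEffUm"]],
    numeric(1))
  expect_true(all(diff(af) < 0))
  expect_true(all(diff(sct) > 0))
})

test_that("mean image intensity is non-decreasing in dye amount", {
  amounts <- c(0, 40, 120, 240)
  means <- vapply(amounts, function(a) {
    p <- quickParams(dyeAmount = a)
    mean(pixels(generateSectionImage(p, seed = 21)$image))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("ground truth round-trips the values used for rendering", {
  p <- quickParams(sctUm = 25, hydrationIndex = 0.3, dyeAmount = 80)
  r <- generateSectionImage(p, seed = 5)
  eff <- trueValues(r$truth)
  expect_equal(eff[["sctEffUm"]], 25 * (0.8 + 0.4 * 0.3))
  expect_equal(eff[["afScEff"]], p@afScLevel * (1.2 - 0.4 * 0.3))
  expect_equal(eff[["dyeAmount"]], 80)
  expect_equal(eff[["noiseSd"]], p@noiseSd)
  expect_identical(r$truth@seed, 5L)
  expect_length(trueSurfaceRows(r$truth), p@imageWidthPx)
})

test_that("a full study meets the image-count floor per condition", {
  m <- StudyManifest()      # 3 ears, 12 conditions, >= 12 cuts, >= 40 images
  expect_length(m@presets, 12L)
  st <- generateStudy(m, quickParams(), seed = 2)
  tab <- table(st@truth$condition)
  expect_equal(length(tab), 12L)
  expect_true(all(tab >= 120L))
  ## every biopsy spreads its images over the minimum number of cuts
  cuts <- aggregate(cut ~ ear + condition, st@truth,
                    function(x) length(unique(x)))
  expect_true(all(cuts$cut >= m@minCuts))
})

test_that("a minimal one-cell design yields exactly one image", {
  m <- StudyManifest(ears = "e1",
                     presets = list(ConditionPreset(1, "hydrophilic",
                                                    "during")),
                     minCuts = 1L, minImages = 1L)
  st <- generateStudy(m, quickParams(), seed = 1)
  expect_length(st@images, 1L)
  expect_identical(nrow(st@truth), 1L)
})

test_that("study generation is deterministic in the root seed", {
  m <- tinyManifest()
  s1 <- generateStudy(m, quickParams(), seed = 77)
  s2 <- generateStudy(m, quickParams(), seed = 77)
  expect_identical(s1@truth, s2@truth)
  expect_identical(pixels(s1@images[[3]]), pixels(s2@images[[3]]))
})

test_that("manifest validity enforces the design structure", {
  expect_error(StudyManifest(presets = list(
    ConditionPreset(2, "hydrophilic", "after"))), "control")
  expect_error(StudyManifest(presets = list(
    ConditionPreset(1, "hydrophilic", "after", label = "x"),
    ConditionPreset(2, "hydrophilic", "after", label = "x"))), "unique")
  expect_error(ConditionPreset(1, "hydrophilic", "after",
                               modifiers = c(dye_amount = 0.5)),
               "control presets")
})

test_that("datasets round-trip through disk with bit depth preserved", {
  dir <- withr::local_tempdir()
  m <- tinyManifest(ears = "e1", minCuts = 1L, minImages = 2L)
  st <- generateStudy(m, quickParams(bitDepth = 16L, noiseSd = 30,
                                     afScLevel = 9000,
                                     afTissueLevel = 6000,
                                     dyeAmount = 20000), seed = 9)
  paths <- writeDataset(st, dir)
  expect_length(paths$images, 4L)
  expect_true(file.exists(paths$truth))
  expect_true(file.exists(paths$manifest))
  expect_error(writeDataset(st, dir), "overwrite")

  back <- readDataset(dir)
  expect_length(back@images, 4L)
  for (i in seq_along(back@images)) {
    orig <- st@images[[i]]
    re <- back@images[[which(back@truth$image_id == orig@imageId)]]
    expect_identical(unname(pixels(re)), unname(round(pixels(orig))))
    expect_lte(max(pixels(re)), 65535)
  }
  ## metrics computed on both are identical
  thr <- 12000
  mo <- measureImage(st@images[[1]], thr)
  mr <- measureImage(back@images[[which(back@truth$image_id ==
                                          st@images[[1]]@imageId)]], thr)
  expect_equal(mo$row$arosa, mr$row$arosa)
  expect_equal(mo$row$mpd_um, mr$row$mpd_um)
  expect_equal(mo$row$sct_um, mr$row$sct_um)
})
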