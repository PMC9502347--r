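## small helper: a metrics table for given conditions/values
mkMetrics <- function(cond, arosa, ear = "e1") {
  n <- length(arosa)
  data.frame(image_id = sprintf("%s_%03d", cond, seq_len(n)),
             ear = rep_len(ear, n), condition = cond,
             sct_um = 20, af_sc = 50, arosa = arosa, mpd_um = 30,
             stringsAsFactors = FALSE)
}

twoCondManifest <- function() {
  StudyManifest(ears = "e1",
                presets = list(ConditionPreset(1, "hydrophilic", "after"),
                               ConditionPreset(3, "hydrophilic", "after")),
                minCuts = 1L, minImages = 3L)
}

test_that("condition aggregation reports n, mean and SD per metric", {
  m <- twoCondManifest()
  tab <- rbind(mkMetrics("s1_hydrophilic_after", c(10, 10, 10)),
               mkMetrics("s3_hydrophilic_after", c(10, 10, 10)))
  agg <- aggregateMetrics(tab, m)
  expect_identical(agg$conditions$n_images, c(3L, 3L))
  expect_equal(agg$conditions$arosa_mean, c(10, 10))
  expect_equal(agg$conditions$arosa_sd, c(0, 0))
  ## two conditions sharing identical data give identical summaries
  same <- agg$conditions[, !(names(agg$conditions) %in%
                               c("condition", "section"))]
  expect_equal(same[1, ], same[2, ], ignore_attr = TRUE)
})

test_that("aggregation is permutation-invariant and checks the manifest", {
  m <- twoCondManifest()
  tab <- rbind(mkMetrics("s1_hydrophilic_after", c(5, 8, 11)),
               mkMetrics("s3_hydrophilic_after", c(1, 2, 3)))
  a1 <- aggregateMetrics(tab, m)
  a2 <- aggregateMetrics(tab[sample.int(nrow(tab)), ], m)
  expect_equal(a1$conditions, a2$conditions)

  expect_error(aggregateMetrics(mkMetrics("nonexistent", 1:3), m),
               "no manifest cell")
  expect_error(
    aggregateMetrics(mkMetrics("s1_hydrophilic_after", 1:3), m),
    "zero images")
  expect_warning(aggregateMetrics(rbind(
    mkMetrics("s1_hydrophilic_after", 1:2),
    mkMetrics("s3_hydrophilic_after", 1:3)), m), "below the design minimum")
})

test_that("control normalization maps the control to exactly 100%", {
  m <- twoCondManifest()
  tab <- rbind(mkMetrics("s1_hydrophilic_after", c(38, 40, 42)),
               mkMetrics("s3_hydrophilic_after", c(12.8, 12.8, 12.8)))
  agg <- aggregateMetrics(tab, m)
  rel <- relativeToControl(agg$conditions)
  ctrl <- rel[rel$section == 1, ]
  expect_identical(ctrl$rel_arosa, 100)
  expect_identical(ctrl$rel_mpd_um, 100)
  ## 12.8 of control mean 40 -> 32.0%
  expect_equal(rel$rel_arosa[rel$section == 3], 32)
  ## RSD = 100 * SD / mean of the condition itself
  expect_equal(ctrl$rsd_arosa, 100 * sd(c(38, 40, 42)) / 40)

  ## 32 of 40 -> 80%
  tab2 <- rbind(mkMetrics("s1_hydrophilic_after", c(40, 40, 40)),
                mkMetrics("s3_hydrophilic_after", c(32, 32, 32)))
  rel2 <- relativeToControl(aggregateMetrics(tab2, m)$conditions)
  expect_equal(rel2$rel_arosa[rel2$section == 3], 80)

  ## treated identical to control -> 100%
  tab3 <- rbind(mkMetrics("s1_hydrophilic_after", c(7, 9, 11)),
                mkMetrics("s3_hydrophilic_after", c(7, 9, 11)))
  rel3 <- relativeToControl(aggregateMetrics(tab3, m)$conditions)
  expect_equal(rel3$rel_arosa, c(100, 100))

  ## a zero control mean leaves the normalization undefined
  tab4 <- rbind(mkMetrics("s1_hydrophilic_after", c(0, 0, 0)),
                mkMetrics("s3_hydrophilic_after", c(1, 2, 3)))
  expect_error(relativeToControl(aggregateMetrics(tab4, m)$conditions),
               "not positive")
})

test_that("compartment classification reproduces the worked boundary cases", {
  calls <- classifyCompartment(c(150, 80, 10), 15)
  expect_identical(as.character(calls$compartment),
                   c("transdermal", "viable_epidermis", "within_SC"))
  expect_error(classifyCompartment(-1, 10), "negative")
  expect_error(classifyCompartment(10, NA), "finite")
})

test_that("compartment calls are exhaustive and mutually exclusive", {
  set.seed(31)
  mpd <- runif(500, 0, 300)
  sct <- runif(500, 0, 60)
  epi <- 110
  calls <- classifyCompartment(mpd, sct, epi)
  expect_false(anyNA(calls$compartment))
  manual <- ifelse(mpd <= sct, "within_SC",
                   ifelse(mpd <= epi, "viable_epidermis", "transdermal"))
  expect_identical(as.character(calls$compartment), manual)
  ## boundary values resolve deterministically to the shallower compartment
  expect_identical(
    as.character(classifyCompartment(c(15, 110), c(15, 15))$compartment),
    c("within_SC", "viable_epidermis"))
})
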