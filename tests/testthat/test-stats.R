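test_that("Shapiro-Wilk checks behave under the null and refuse degenerates", {
  ## under a true normal generator most repeats should not reject
  keep <- vapply(1:100, function(i) {
    set.seed(i)
    testNormality(list(g = rnorm(100)))$p >= 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.90)

  ## refusal codes: constant data, tiny n, huge n
  res <- testNormality(list(a = rep(3, 10), b = c(1, 2), c = rnorm(20)))
  expect_identical(res$code, c("degenerate", "too_few", "ok"))
  expect_identical(res$normal[1:2], c(FALSE, FALSE))
  expect_identical(testNormality(list(g = rnorm(6000)))$code, "too_large")

  ## a strongly bimodal two-point sample is flagged non-normal
  bi <- c(rep(0, 25), rep(1, 25))
  resBi <- testNormality(list(g = bi))
  expect_lt(resBi$p, 0.05)
  expect_equal(resBi$p, 7.143777e-10, tolerance = 1e-4)  # reference value
})

test_that("Levene's test detects inhomogeneity and holds its level", {
  ## identical multisets -> F = 0, p = 1
  g <- list(a = c(1, 5, 9, 2), b = c(9, 1, 2, 5))
  lev <- testVarianceHomogeneity(g)
  expect_equal(lev$statistic, 0)
  expect_equal(lev$p, 1)
  expect_error(testVarianceHomogeneity(list(a = 1, b = rnorm(5))), "n >= 2")

  ## variances 1 vs 25 at n = 50: essentially always detected
  hits <- vapply(1:100, function(i) {
    set.seed(i)
    testVarianceHomogeneity(list(a = rnorm(50, 0, 1),
                                 b = rnorm(50, 0, 5)))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  ## type-I error of the Levene gate alone under the null
  rej <- vapply(1:2000, function(i) {
    set.seed(20000 + i)
    testVarianceHomogeneity(list(a = rnorm(20), b = rnorm(20),
                                 c = rnorm(20)))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Games-Howell matches reference values", {
  ## frozen from an independent implementation (pingouin 0.6.1)
  gh <- gamesHowellTest(list(a = c(1, 2, 3, 4, 5, 6),
                             b = c(2, 4, 6, 8, 10, 12),
                             c = c(1, 1, 2, 2, 3, 10)))
  expect_identical(gh$group1, c("a", "a", "b"))
  expect_identical(gh$group2, c("b", "c", "c"))
  expect_equal(gh$estimate, c(-3.5, 1 / 3, 23 / 6))
  expect_equal(gh$statistic, c(-2.049390, 0.208969, 1.849793),
               tolerance = 1e-5)
  expect_equal(gh$df, c(7.352941, 7.732722, 9.925434), tolerance = 1e-5)
  expect_equal(gh$p_adj, c(0.167547, 0.976288, 0.203795), tolerance = 1e-4)
})

test_that("Dunn's test matches an independent rank computation", {
  ## frozen from an independent tie-corrected rank calculation
  dn <- dunnTest(list(a = 1:5, b = 3:7, c = 6:10), p.adjust.method = "holm")
  expect_equal(dn$statistic, c(-1.278513, -3.089739, -1.811226),
               tolerance = 1e-5)
  expect_equal(dn$p_adj, c(0.20106873, 0.00600998, 0.14021167),
               tolerance = 1e-6)
  ## unadjusted option leaves the raw two-sided p values
  dn0 <- dunnTest(list(a = 1:5, b = 3:7, c = 6:10), p.adjust.method = "none")
  expect_equal(dn0$p_adj[2], 0.00200333, tolerance = 1e-5)
})

test_that("the decision tree selects the paths the assumptions dictate", {
  ## identical groups: no significant pairs whatever the path
  g0 <- list(a = c(1, 4, 2, 8, 5, 7), b = c(1, 4, 2, 8, 5, 7),
             c = c(1, 4, 2, 8, 5, 7))
  cmp0 <- compareGroups(g0)
  expect_gt(cmp0@p, 0.05)
  expect_true(all(cmp0@pairwise$stars == "ns"))

  ## normal, equal variance, one mean shifted by 3 SD -> ANOVA + Tukey
  set.seed(5)
  gs <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 3))
  cmpS <- compareGroups(gs)
  expect_identical(cmpS@omnibus, "ANOVA")
  expect_identical(cmpS@postHoc, "Tukey")
  pw <- cmpS@pairwise
  shifted <- (pw$group1 == "c") | (pw$group2 == "c")
  expect_true(all(pw$stars[shifted] != "ns"))
  expect_true(all(pw$stars[!shifted] == "ns"))

  ## normal but inhomogeneous variances -> Welch + Games-Howell
  set.seed(8)
  gv <- list(a = rnorm(40, sd = 1), b = rnorm(40, sd = 6),
             c = rnorm(40, sd = 1))
  cmpV <- compareGroups(gv)
  expect_identical(cmpV@omnibus, "Welch-ANOVA")
  expect_identical(cmpV@postHoc, "Games-Howell")

  ## strongly skewed group -> Kruskal-Wallis + Dunn, recorded in the trace
  set.seed(9)
  gh <- list(a = rnorm(30), b = rnorm(30), c = rlnorm(30, sdlog = 1.5))
  cmpH <- compareGroups(gh)
  expect_identical(cmpH@omnibus, "Kruskal-Wallis")
  expect_identical(cmpH@postHoc, "Dunn")
  expect_true(any(grepl("non-parametric path", cmpH@trace)))

  ## a constant group cannot be tested for normality -> non-parametric
  gc <- list(a = rep(5, 10), b = rnorm(10), c = rnorm(10))
  cmpC <- compareGroups(gc)
  expect_identical(cmpC@omnibus, "Kruskal-Wallis")
  expect_true(any(grepl("refused \\(degenerate\\)", cmpC@trace)))
})

test_that("every comparison yields one omnibus/post hoc pairing and a trace", {
  pairing <- c("ANOVA" = "Tukey", "Welch-ANOVA" = "Games-Howell",
               "Kruskal-Wallis" = "Dunn")
  set.seed(77)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    gen <- sample(c("normal", "varied", "lognormal", "rounded"), 1)
    groups <- lapply(seq_len(k), function(j) {
      n <- sample(5:30, 1)
      switch(gen,
             normal = rnorm(n),
             varied = rnorm(n, sd = j),
             lognormal = rlnorm(n),
             rounded = round(runif(n, 0, 4)))
    })
    names(groups) <- paste0("g", seq_len(k))
    if (any(vapply(groups, sd, numeric(1)) == 0) && k < 2) next
    cmp <- compareGroups(groups)
    expect_identical(cmp@postHoc, unname(pairing[cmp@omnibus]))
    expect_gte(length(cmp@trace), k + 1L)
    expect_true(all(cmp@pairwise$p_adj >= 0 & cmp@pairwise$p_adj <= 1))
    expect_equal(nrow(cmp@pairwise), choose(k, 2))
  }
})

test_that("two-group tests choose t or Mann-Whitney appropriately", {
  ## identical groups: p ~ 1, no stars
  x <- c(2, 4, 6, 8, 10, 3, 5)
  same <- pairwiseTest(x, x)
  expect_gt(same$p, 0.9)
  expect_identical(same$stars, "ns")

  ## well-separated normal groups: highly significant t test
  set.seed(12)
  sep <- pairwiseTest(rnorm(50, 0), rnorm(50, 2))
  expect_match(sep$method, "t$|^t")
  expect_lt(sep$p, 0.001)
  expect_identical(sep$stars, "***")

  ## skewed ordinal data with ties route to the Mann-Whitney test and match
  ## the tie-corrected reference p (scipy 1.17 asymptotic, continuity-corrected)
  ga <- c(rep(1, 8), 2, 2, 2, 9, 10, 11)
  gb <- c(rep(2, 6), 3, 3, 4, 10, 12, 13, 14, 15)
  mw <- pairwiseTest(ga, gb)
  expect_identical(mw$method, "Mann-Whitney")
  expect_equal(unname(mw$statistic), 37.5)
  expect_equal(mw$p, 0.004539431025807828, tolerance = 1e-10)

  expect_error(pairwiseTest(1, 1:5), "two observations")
})

test_that("significance stars follow the strict step map", {
  expect_identical(annotateSignificance(c(0.0005, 0.005, 0.03, 0.05, 0.5)),
                   c("***", "**", "*", "ns", "ns"))
  ## strict boundaries
  expect_identical(annotateSignificance(c(0.001, 0.01)), c("**", "*"))
  expect_error(annotateSignificance(1.2), "\\[0, 1\\]")
  expect_error(annotateSignificance(-0.1), "\\[0, 1\\]")
})
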