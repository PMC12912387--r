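test_that("Spearman correlation matches hand-ranked values and is monotone-invariant", {
  ft <- data.frame(x = c(1, 2, 3), y = c(3, 1, 2), z = exp(c(1, 2, 3)),
                   const = c(1, 1, 1), w = c(0.1, 5, 9, 2)[1:3])
  sp <- spearmanMatrix(cbind(ft, pad = rnorm(3)))
  r_xy <- sp$r[sp$var1 == "x" & sp$var2 == "y"]
  expect_equal(r_xy, -0.5)  # 1 - 6*6/(3*8)
  r_xz <- sp$r[sp$var1 == "x" & sp$var2 == "z"]
  expect_equal(r_xz, 1)     # monotone transform leaves ranks unchanged
  expect_true(is.na(sp$r[sp$var1 == "const" | sp$var2 == "const"][1]))
})

test_that("circular unwrapping removes the midnight discontinuity before ranking", {
  set.seed(51)
  base <- rnorm(40, 0, 1.2)
  ft <- data.frame(phase = (base) %% 24,  # phases straddling 0/24
                   driver = base + rnorm(40, 0, 0.3))
  raw <- spearmanMatrix(ft)  # uncentered replication mode
  cut4 <- spearmanMatrix(ft, circular = "phase", circular_cut = 12)
  expect_gt(cut4$r, raw$r)
  expect_gt(cut4$r, 0.8)
})

test_that("regression lines carry exact solutions and a permutation-calibrated p", {
  lr <- linregressWithP(c(0, 1, 2), c(0, 2, 4))
  expect_equal(lr$slope, 2)
  expect_equal(lr$intercept, 0)
  expect_true(lr$perfect_fit); expect_equal(lr$p, 0)
  expect_equal(linregressWithP(1:5, 7 - (1:5))$slope, -1)
  expect_error(linregressWithP(rep(1, 5), rnorm(5)), "constant")
  set.seed(52)
  x <- rnorm(20); y <- 3 * x + rnorm(20)
  lr <- linregressWithP(x, y)
  expect_lt(abs(lr$slope - 3), 3 * lr$stderr)
  perm <- replicate(4000, {
    fp <- lm(sample(y) ~ x)
    abs(coef(fp)[2])
  })
  p_perm <- mean(perm >= abs(lr$slope))
  expect_lt(abs(lr$p - p_perm), 3 * sqrt(max(lr$p, 1 / 4000) / 4000) + 0.005)
})

test_that("mutual information matches entropy limits and stays near zero under independence", {
  x <- as.numeric(1:64)
  expect_equal(mutualInformation(x, x, n_bins = 4), log(4), tolerance = 1e-12)
  expect_equal(mutualInformation(x, rev(x), n_bins = 4), log(4), tolerance = 1e-12)
  set.seed(53)
  mis <- replicate(8, mutualInformation(runif(1000), runif(1000)))
  expect_lt(mean(mis), 0.05)
  expect_true(all(mis >= 0))
  # MI(x, x) equals the discretized marginal entropy for any bin count
  for (k in c(2, 5, 8)) {
    x2 <- rnorm(120)
    expect_equal(mutualInformation(x2, x2, n_bins = k), log(k), tolerance = 1e-9)
  }
  expect_error(mutualInformation(1:20, 1:20, n_bins = 1), "n_bins")
})

test_that("MIC scores functional, null and noisy relationships in the expected order", {
  set.seed(54)
  x <- runif(60)
  expect_equal(maximalInformationCoefficient(x, x)$mic, 1)
  expect_equal(maximalInformationCoefficient(x, -2 * x + 1)$mic, 1)
  nulls <- replicate(5, maximalInformationCoefficient(runif(200), runif(200))$mic)
  expect_lt(mean(nulls), 0.3)
  xg <- seq(0, 1, length.out = 120)
  clean <- maximalInformationCoefficient(xg, sin(2 * pi * xg))$mic
  noisy <- maximalInformationCoefficient(xg, sin(2 * pi * xg) + rnorm(120, 0, 1.5))$mic
  expect_gte(clean, noisy)
  expect_gt(clean, 0.8)
  deg <- maximalInformationCoefficient(rep(1, 30), rnorm(30))
  expect_true(deg$degenerate); expect_equal(deg$mic, 0)
})

test_that("the hill-climbing MIC search is bounded by the exhaustive tiny-n oracle", {
  set.seed(55)
  for (i in 1:4) {
    x <- rnorm(12); y <- 0.5 * x + rnorm(12, 0, 0.7)
    # restrict both searches to the same grid family (r*c <= 9)
    impl <- maximalInformationCoefficient(x, y, grid_limit_exponent = log(9.5) / log(12))
    oracle <- micExhaustiveTiny(x, y, max_bins = 4L, max_cells = 9L)
    expect_lte(impl$mic, oracle + 1e-9)
    expect_gt(impl$mic, 0)
  }
})

test_that("L/E ratios aggregate fields per slide and flag undefined slides", {
  d <- data.frame(participant = "P01", day = 1L, time_h = 9,
                  field_index = 1:2, leukocytes = c(2L, 3L), epithelial = c(1L, 4L))
  lr <- leRatio(CellCountTable(d))
  expect_equal(lr$le_ratio, 1)  # 5/5
  d2 <- data.frame(participant = "P01", day = 1L, time_h = c(9, 9, 13, 13),
                   field_index = c(1:2, 1:2), leukocytes = c(4L, 4L, 1L, 2L),
                   epithelial = c(4L, 4L, 0L, 0L))
  lr2 <- leRatio(CellCountTable(d2))
  expect_equal(lr2$le_ratio[lr2$time_h == 9], 1)
  expect_true(is.na(lr2$le_ratio[lr2$time_h == 13]))
  expect_false(lr2$defined[lr2$time_h == 13])
  # share-to-ratio conversion: 64% leukocytes implies L/E = 16/9
  d3 <- data.frame(participant = "P01", day = 1L, time_h = 9,
                   field_index = 1:8, leukocytes = 64L, epithelial = 36L)
  expect_equal(leRatio(CellCountTable(d3))$le_ratio, 16 / 9)
})

test_that("one-way ANOVA reproduces the classical F decomposition and its null level", {
  res <- onewayAnova(list(A = c(1, 2), B = c(3, 4)))
  expect_equal(res$f, 8)  # SSB 4 (df 1) over SSW 1 (df 2)
  expect_equal(res$p, pf(8, 1, 2, lower.tail = FALSE))
  base <- oneway.test(v ~ g, data.frame(v = c(1, 2, 3, 4), g = c("A", "A", "B", "B")),
                      var.equal = TRUE)
  expect_equal(res$f, unname(base$statistic))
  set.seed(56)
  rej <- mean(replicate(600, {
    onewayAnova(list(rnorm(5), rnorm(5), rnorm(5)))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 2.5 * sqrt(0.05 * 0.95 / 600))
  deg <- onewayAnova(list(c(1, 1), c(1, 1)))
  expect_true(deg$degenerate)
})

test_that("MEQ chronotype cut-offs follow the standard convention", {
  expect_equal(classifyChronotype(41), "evening")
  expect_equal(classifyChronotype(42), "intermediate")
  expect_equal(classifyChronotype(58), "intermediate")
  expect_equal(classifyChronotype(59), "morning")
  expect_equal(classifyChronotype(70), "morning")
  expect_error(classifyChronotype(15), "16\\.\\.86")
  expect_error(classifyChronotype(87), "16\\.\\.86")
  # cohort MEQ distribution centred in the intermediate band
  g <- generateCohort(cohortConfig(n_participants = 60, seed = 8))
  expect_gt(mean(g$participants$chronotype == "intermediate"), 0.5)
})

test_that("the feature table assembles all layers with circular columns flagged", {
  g <- generateCohort(cohortConfig(n_participants = 6, seed = 14))
  es <- deltaDeltaCt(g$ct)
  ft <- cohortFeatures(es, hormones = g$hormones, participants = g$participants,
                       cells = g$cells)
  expect_equal(nrow(ft), 6L)
  expect_true(all(c("ARNTL1_mesor", "ARNTL1_acrophase_h", "cortisol_mesor",
                    "cortisol_acrophase_h", "melatonin", "bedtime_h", "meq",
                    "le_ratio") %in% names(ft)))
  circ <- attr(ft, "circular_columns")
  expect_true(all(grepl("acrophase", circ)))
  expect_true("cortisol_acrophase_h" %in% circ)
  expect_true(all(is.finite(ft$le_ratio)))
})
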