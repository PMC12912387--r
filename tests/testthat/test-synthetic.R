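test_that("cohort generation is deterministic and validates its config", {
  cc <- cohortConfig(n_participants = 4, seed = 42)
  expect_identical(generateCohort(cc), generateCohort(cc))
  expect_error(cohortConfig(n_participants = 4), "seed")
  expect_error(cohortConfig(n_participants = 4, seed = 1,
                            genes = data.frame(gene = "X", mesor = -1,
                                               rel_amplitude = 0.4,
                                               acrophase_h = 10,
                                               acrophase_sd_h = 1)),
               "positive")
  expect_error(geneParams("X", mesor = 1, rel_amplitude = 1.2, acrophase_h = 3))
})

test_that("generated tables have the protocol shape and a complete truth table", {
  cc <- cohortConfig(n_participants = 5, seed = 9)
  g <- generateCohort(cc)
  d <- ctData(g$ct)
  # 5 participants x 2 days x 4 times x (3 targets + GAPDH)
  expect_equal(nrow(d), 5 * 2 * 4 * 4)
  expect_setequal(unique(d$gene), c("ARNTL1", "PER2", "NR1D1", "GAPDH"))
  expect_equal(nrow(g$truth), 5 * 3)      # one row per participant x gene
  expect_true(all(c("bedtime_h", "cortisol_acrophase_h", "melatonin") %in%
                    names(g$truth)))
  expect_equal(nrow(g$participants), 5L)
  # 8 fields per slide
  cells <- cellCounts(g$cells)
  expect_true(all(table(cells$participant, cells$day, cells$time_h) == 8))
  # cortisol: 7 offsets per day; melatonin: one value per day
  cort <- Filter(function(h) analyte(h) == "cortisol", g$hormones)
  expect_true(all(vapply(cort, function(h) all(table(hormoneSamples(h)$day) == 7), TRUE)))
  mel <- Filter(function(h) analyte(h) == "melatonin", g$hormones)
  expect_true(all(vapply(mel, function(h) all(table(hormoneSamples(h)$day) == 1), TRUE)))
})

test_that("dense series have the documented point count and noise behaviour", {
  gp <- geneParams("ARNTL1", mesor = 1, rel_amplitude = 0.4, acrophase_h = 18)
  s <- generateDenseSeries(gp, interval_h = 3, duration_h = 30, noise_sd = 0, seed = 1)
  p <- seriesPoints(s)
  expect_equal(nrow(p), 11L)  # floor(30/3) + 1
  t <- absoluteTime(p$day, p$time_h)
  expect_equal(p$fold_change, 1 + 0.4 * cos(2 * pi * (t - 18) / 24), tolerance = 1e-12)
  # different seeds: same mean curve, different noise
  reps <- sapply(1:40, function(s) seriesPoints(
    generateDenseSeries(gp, 3, 30, noise_sd = 0.1, seed = 100 + s))$fold_change)
  expect_gt(sd(reps[1, ]), 0)
  expect_lt(max(abs(rowMeans(reps) - (1 + 0.4 * cos(2 * pi * (t - 18) / 24)))), 0.08)
  expect_error(generateDenseSeries(gp, interval_h = 0, duration_h = 30))
})

test_that("the induced cortisol-melatonin coupling is detectable at cohort scale", {
  cc <- cohortConfig(n_participants = 200, seed = 5)
  g <- generateCohort(cc)
  tr <- unique(g$truth[, c("participant", "cortisol_mesor", "melatonin")])
  ct <- cor.test(tr$cortisol_mesor, tr$melatonin, method = "spearman")
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("truth acrophases track bedtime with the configured positive slope", {
  cc <- cohortConfig(n_participants = 150, seed = 6)
  g <- generateCohort(cc)
  tr <- g$truth[g$truth$gene == "ARNTL1", ]
  ct <- cor.test(centerPhase(tr$acrophase_h, 18), tr$bedtime_h, method = "spearman")
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
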