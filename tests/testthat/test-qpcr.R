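test_that("two-step normalization reproduces the hand-computed fold changes", {
  ct <- makeCtFixture(c(25, 24, 26, 25))
  p <- seriesPoints(deltaDeltaCt(ct))
  # dCT = (5,4,6,5); ddCT = (0,-1,1,0); 2^(-ddCT) = (1,2,0.5,1)
  expect_equal(p$fold_change, c(1, 2, 0.5, 1))
  expect_equal(p$rel_expr, 2^-c(5, 4, 6, 5))
  # target == reference everywhere -> unit fold changes
  ct2 <- makeCtFixture(rep(20, 4))
  expect_equal(seriesPoints(deltaDeltaCt(ct2))$fold_change, rep(1, 4))
})

test_that("fold changes are invariant to constant CT shifts of target or reference", {
  base <- seriesPoints(deltaDeltaCt(makeCtFixture(c(25, 24, 26, 25))))$fold_change
  shifted_target <- seriesPoints(deltaDeltaCt(makeCtFixture(c(25, 24, 26, 25) + 3)))$fold_change
  shifted_ref <- seriesPoints(deltaDeltaCt(
    makeCtFixture(c(25, 24, 26, 25) + 3, ct_ref = rep(23, 4))))$fold_change
  expect_equal(shifted_target, base)   # mean-centering removes the constant
  expect_equal(shifted_ref, base)      # reference shift cancels in dCT... then recentred
})

test_that("the geometric mean of fold changes over the normalization window is 1", {
  set.seed(4)
  for (i in 1:5) {
    ct <- makeCtFixture(rnorm(4, 26, 2), ct_ref = rnorm(4, 20, 0.3))
    fc <- seriesPoints(deltaDeltaCt(ct))$fold_change
    expect_equal(exp(mean(log(fc))), 1, tolerance = 1e-12)
  }
})

test_that("timepoints without a usable reference CT are excluded and logged, not dropped silently", {
  d <- data.frame(participant = "P01", day = 1L, time_h = c(9, 13, 17, 21, 9, 13, 17),
                  gene = c(rep("PER2", 4), rep("GAPDH", 3)),
                  ct = c(25, 24, 26, 25, 20, 20, 20))
  es <- deltaDeltaCt(CtTable(d))
  expect_equal(nrow(seriesPoints(es)), 3L)
  lg <- exclusionLog(es)
  expect_equal(lg$time_h, 21)
  expect_match(lg$reason, "reference")
  # accountability: points in == points out + logged exclusions
  expect_equal(nrow(seriesPoints(es)) + nrow(lg), 4L)
})

test_that("mean expression follows the arithmetic-mean definition and partitions by day", {
  pts <- data.frame(participant = "P01", gene = "PER2",
                    day = rep(1:2, each = 2), time_h = rep(c(9, 13), 2),
                    rel_expr = c(1, 2, 0.5, 1), fold_change = c(1, 2, 0.5, 1))
  es <- ExpressionSeriesSet(pts)
  expect_equal(meanExpression(es), 1.125)
  per_day <- meanExpression(es, window = "per_day")
  expect_equal(unname(per_day), c(1.5, 0.75))
  expect_equal(mean(per_day), 1.125)  # equal counts: day means partition the overall mean
  expect_error(meanExpression(ExpressionSeriesSet(pts[0, ])), "empty")
})

test_that("quantification composed with a noise-free synthetic cohort returns the generating cosine", {
  cc <- cohortConfig(n_participants = 2, ct_noise_sd = 0, day_effect_sd = 0, seed = 7)
  g <- generateCohort(cc)
  p <- seriesPoints(deltaDeltaCt(g$ct))
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    q <- p[p$participant == tr$participant & p$gene == tr$gene, ]
    e <- tr$mesor * (1 + tr$rel_amplitude *
                       cos(2 * pi * (absoluteTime(q$day, q$time_h) - tr$acrophase_h) / 24))
    ratio <- q$fold_change / e
    expect_equal(ratio / ratio[1], rep(1, nrow(q)), tolerance = 1e-9)
  }
})
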