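test_that("a noiseless cosine is interpolated exactly", {
  t <- c(0, 6, 12, 18)
  f <- fitHarmonic(t, 2 + cos(2 * pi * t / 24))
  expect_equal(mesor(f), 2)
  expect_equal(amplitude(f), 1)
  expect_equal(acrophase(f), 0, tolerance = 1e-9)
  expect_true(f@perfect_fit)
  # constant series: zero amplitude, degenerate test p = 1
  fc <- fitHarmonic(t, rep(3, 4))
  expect_equal(amplitude(fc), 0, tolerance = 1e-9)
  expect_equal(fc@lrt_p, 1)
})

test_that("Monte-Carlo recovery: amplitude 1, peak 16 h, noise 0.2", {
  set.seed(11)
  t <- seq(0, 21, by = 3)
  fits <- replicate(500, {
    y <- 5 + cos(2 * pi * (t - 16) / 24) + rnorm(length(t), 0, 0.2)
    f <- fitHarmonic(t, y)
    c(acrophase(f), amplitude(f))
  })
  expect_lt(abs(mean(fits[1, ]) - 16), 0.2)
  expect_lt(abs(mean(fits[2, ]) - 1), 0.05)
})

test_that("OLS matches the grid-search oracle on short series", {
  set.seed(21)
  for (i in 1:4) {
    n <- sample(6:12, 1)
    t <- sort(runif(n, 0, 48))
    y <- 1 + 0.5 * cos(2 * pi * (t - runif(1, 0, 24)) / 24) + rnorm(n, 0, 0.3)
    f <- fitHarmonic(t, y)
    g <- gridSearchHarmonic(t, y, res = 1e-6)
    expect_lt(abs(mesor(f) - g$mu), 1e-4)
    expect_lt(abs(f@a - g$a), 1e-4)
    expect_lt(abs(f@b - g$b), 1e-4)
    expect_lte(f@rss_full, g$rss + 1e-4)
  }
})

test_that("time shifts move the acrophase and nothing else", {
  set.seed(22)
  t <- c(9, 13, 17, 21, 33, 37, 41, 45)
  y <- 1 + 0.4 * cos(2 * pi * (t - 18) / 24) + rnorm(8, 0, 0.1)
  f0 <- fitHarmonic(t, y)
  for (delta in c(3.25, 11, 26)) {
    f1 <- fitHarmonic(t + delta, y)
    expect_equal(acrophase(f1), (acrophase(f0) + delta) %% 24, tolerance = 1e-9)
    expect_equal(amplitude(f1), amplitude(f0), tolerance = 1e-9)
    expect_equal(mesor(f1), mesor(f0), tolerance = 1e-9)
    expect_equal(f1@rss_full, f0@rss_full, tolerance = 1e-9)
    expect_equal(f1@lrt_p, f0@lrt_p, tolerance = 1e-9)
  }
})

test_that("harmonic amplitude equals the generating amplitude; max-min never exceeds twice it", {
  set.seed(23)
  for (i in 1:5) {
    A <- runif(1, 0.2, 2); phi <- runif(1, 0, 24)
    t <- sort(runif(8, 0, 48))
    y <- 3 + A * cos(2 * pi * (t - phi) / 24)
    f <- fitHarmonic(t, y)
    expect_equal(amplitude(f), A, tolerance = 1e-8)
    expect_equal(circularDiff(acrophase(f), phi), 0, tolerance = 1e-7)
    expect_lte(max(y) - min(y), 2 * A + 1e-12)
  }
})

test_that("rhythmicity statistics follow their closed forms and degenerate rules", {
  # n=8, rss ratio e under the likelihood-ratio form: stat 8, p = chi2 tail
  f <- new("HarmonicFit", mu = 1, a = 0.1, b = 0, amplitude = 0.1, acrophase_h = 0,
           period_h = 24, rss_full = 1, rss_null = exp(1), n_points = 8L,
           lrt_stat = NA_real_, lrt_p = NA_real_, lrt_method = "none",
           saturated = FALSE, perfect_fit = FALSE, converged = TRUE, robust = FALSE)
  fc <- rhythmicityTest(f, "chisq")
  expect_equal(fc@lrt_stat, 8)
  expect_equal(fc@lrt_p, pchisq(8, 2, lower.tail = FALSE))  # ~0.0183
  # equal residual sums: stat 0, p 1 under both forms
  f@rss_null <- 1
  expect_equal(rhythmicityTest(f, "chisq")@lrt_p, 1)
  expect_equal(rhythmicityTest(f, "ftest")@lrt_p, 1)
  # saturated 3-point fit: parameters yes, p-value no
  t3 <- c(0, 8, 16)
  f3 <- fitHarmonic(t3, c(1, 2, 1.5))
  expect_true(isSaturated(f3))
  expect_true(is.na(f3@lrt_p))
  expect_equal(f3@rss_full, 0, tolerance = 1e-20)
  # fewer than 3 distinct phases: singular design
  expect_error(fitHarmonic(c(0, 24, 48, 72), c(1, 2, 1, 2)), "singular")
})

test_that("the soft-L1 fit agrees with OLS on clean data and keeps the documented defaults", {
  t <- seq(0, 21, 3)
  y <- 2 + cos(2 * pi * (t - 16) / 24)
  fr <- fitHarmonicRobust(t, y)
  fo <- fitHarmonic(t, y)
  expect_lt(abs(mesor(fr) - mesor(fo)), 1e-6)
  expect_lt(abs(fr@a - fo@a), 1e-6)
  expect_lt(abs(fr@b - fo@b), 1e-6)
  expect_true(fr@converged)
  expect_true(fr@robust)
  # the default start and scale are the published cortisol initialization:
  # an explicit call with those values is identical to the default call
  set.seed(33)
  tc <- c(0, 0.5, 1, 2, 5, 8, 12)
  yc <- 6 + 3 * cos(2 * pi * (tc - 1) / 24) + rnorm(7, 0, 0.4)
  f_default <- fitHarmonicRobust(tc, yc)
  f_explicit <- fitHarmonicRobust(tc, yc, f_scale = 0.1,
                                  x0 = c(a = -0.31084448, b = 2.33838041,
                                         mu = 6.33268443))
  expect_identical(mesor(f_default), mesor(f_explicit))
  expect_identical(acrophase(f_default), acrophase(f_explicit))
})

test_that("robust fitting resists a gross outlier that derails OLS", {
  set.seed(31)
  t <- seq(0, 22, by = 2)
  y <- 2 + cos(2 * pi * (t - 16.7) / 24) + rnorm(length(t), 0, 0.05)
  i <- 5; y[i] <- y[i] + 10
  fr <- fitHarmonicRobust(t, y)
  fo <- fitHarmonic(t, y)
  expect_lt(circularDiff(acrophase(fr), 16.7), 0.2)
  expect_gt(circularDiff(acrophase(fo), 16.7), circularDiff(acrophase(fr), 16.7))
})

test_that("circular phase distance respects midnight adjacency", {
  expect_equal(circularDiff(23.5, 0.5), 1)
  expect_equal(circularDiff(7.25, 7.25), 0)
  expect_equal(circularDiff(6, 18), 12)
  set.seed(32)
  p1 <- runif(50, 0, 24); p2 <- runif(50, 0, 24)
  expect_true(all(circularDiff(p1, p2) >= 0 & circularDiff(p1, p2) <= 12))
  expect_equal(circularDiff(p1, p2), circularDiff(p2, p1))
})

test_that("descriptive summaries report range, first peak and relative amplitude", {
  pts <- data.frame(participant = "P01", gene = "PER2", day = 1L,
                    time_h = c(9, 13, 17, 21), rel_expr = c(1, 3, 2, 5),
                    fold_change = c(1, 3, 2, 5))
  cs <- circadianSummary(pts)
  expect_equal(cs$max_min, 4)
  expect_equal(cs$max_val, 5)
  expect_equal(cs$mean_val, 2.75)
  expect_equal(cs$peak_time_h, 21)
  expect_equal(cs$rel_amplitude, 4 / 2.75)
  # tie for the maximum resolves to the first peak
  pts$fold_change <- c(5, 3, 2, 5)
  expect_equal(circadianSummary(pts)$peak_time_h, 9)
  # constant series
  pts$fold_change <- rep(2, 4)
  expect_equal(circadianSummary(pts)$max_min, 0)
  expect_equal(circadianSummary(pts)$rel_amplitude, 0)
})

test_that("interval restriction keeps inclusive-boundary points of the waking windows", {
  t <- seq(0, 48, by = 2)
  pts <- data.frame(participant = "P01", gene = "PER2",
                    day = as.integer(t %/% 24 + 1), time_h = t %% 24,
                    rel_expr = 1, fold_change = 1)
  pts <- pts[pts$time_h < 24 & absoluteTime(pts$day, pts$time_h) <= 48, ]
  kept <- restrictToInterval(pts, list(c(4, 14), c(26, 38)))
  expect_equal(nrow(kept), 13L)  # 6 + 7 inclusive boundary points
  expect_equal(nrow(restrictToInterval(pts, list(c(0, 100)))), nrow(pts))
  deg <- restrictToInterval(pts, list(c(0, 0)))
  expect_equal(absoluteTime(deg$day, deg$time_h), 0)
  expect_error(restrictToInterval(pts, list(c(4, 14), c(10, 20))), "non-overlapping")
  expect_warning(restrictToInterval(pts, list(c(100, 101))), "empty")
})
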