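gpEvening <- geneParams("ARNTL1", mesor = 1, rel_amplitude = 0.4, acrophase_h = 18)

test_that("design enumeration covers the grid and always includes the protocol schedule", {
  ds <- enumerateDesigns(points_per_day = 4, n_days = 1, wake_window = c(9, 21),
                         grid_step_h = 4)
  sigs <- vapply(ds, function(d) paste(d$times_h, collapse = ","), "")
  expect_true("9,13,17,21" %in% sigs)
  # protocol design appended with its 2-day layout
  proto <- Filter(function(d) d$n_days == 2L, ds)
  expect_equal(proto[[1]]$times_h, c(9, 13, 17, 21))
  # pigeonhole: more points than grid positions -> no within-day design for that k
  ds2 <- enumerateDesigns(points_per_day = 5, n_days = 1, wake_window = c(9, 21),
                          grid_step_h = 4)
  expect_true(all(vapply(ds2, function(d) d$points_per_day != 5 || d$n_days == 2L, TRUE)))
  # k=3 on a 6 h grid: exactly one evenly spaced design {9,15,21}
  ds3 <- enumerateDesigns(points_per_day = 3, n_days = 1, wake_window = c(9, 21),
                          grid_step_h = 6)
  k3 <- Filter(function(d) d$points_per_day == 3L, ds3)
  expect_length(k3, 1L)
  expect_equal(k3[[1]]$times_h, c(9, 15, 21))
  expect_error(enumerateDesigns(3, wake_window = c(21, 9)), "empty")
})

test_that("noise-free designs recover the truth exactly and saturated designs never succeed", {
  dense <- samplingDesign(seq(9, 21, 3), n_days = 2)
  ev <- evaluateDesign(gpEvening, dense, noise_sd = 0, n_replicates = 5, seed = 2)
  expect_equal(ev$median_phase_error_h, 0, tolerance = 1e-6)
  expect_equal(ev$feasible_fraction, 1)
  expect_true(ev$success)
  # three points in one day: fit saturated, never successful, at any noise
  k3 <- spanDesign(3)
  for (ns in c(0, 0.1, 0.5)) {
    ev3 <- evaluateDesign(gpEvening, k3, noise_sd = ns, n_replicates = 10, seed = 3)
    expect_equal(ev3$feasible_fraction, 0)
    expect_false(ev3$success)
  }
  # any non-saturated design at vanishing noise: phase error below 1e-6 h
  ev4 <- evaluateDesign(gpEvening, spanDesign(4), noise_sd = 1e-12,
                        n_replicates = 5, seed = 4)
  expect_lt(ev4$median_phase_error_h, 1e-6)
})

test_that("success is monotone in sampling density up to Monte-Carlo slack", {
  evals <- do.call(rbind, lapply(3:7, function(k)
    evaluateDesign(gpEvening, spanDesign(k), noise_sd = 0.15,
                   n_replicates = 60, seed = 40 + k)))
  det <- evals$detection_rate
  se <- sqrt(pmax(det * (1 - det), 0.01) / 60)
  feasible <- evals$feasible_fraction == 1
  expect_true(all(diff(det[feasible]) > -2 * (se[feasible][-1] + se[feasible][-sum(feasible)])))
})

test_that("the minimal sufficient design reports per day count and handles all-fail", {
  evals <- data.frame(points_per_day = c(3, 4, 5, 3, 4), n_days = c(1, 1, 1, 2, 2),
                      success = c(FALSE, TRUE, TRUE, FALSE, FALSE))
  ms <- minimalSufficientDesign(evals)
  expect_equal(ms$min_points_per_day[ms$n_days == 1], 4)
  expect_true(is.na(ms$min_points_per_day[ms$n_days == 2]))
})

test_that("five points spread over two days suffice at moderate noise", {
  d5 <- samplingOffsets(day = c(1, 1, 1, 2, 2), time_h = c(9, 15, 21, 12, 18))
  ev <- evaluateDesign(gpEvening, d5, noise_sd = 0.1, n_replicates = 100, seed = 77)
  expect_equal(ev$feasible_fraction, 1)
  expect_true(ev$success)
})
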