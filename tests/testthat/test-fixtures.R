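test_that("Poisson trains have the requested rate and count statistics", {
  tr <- poisson_train(50, 20000, n_trains = 40, seed = 3)
  rate <- nrow(tr) / (40 * 20)  # spikes / (trains * seconds)
  expect_equal(rate, 50, tolerance = 0.05)
  expect_true(all(tr$t_ms >= 0 & tr$t_ms <= 20000))
  expect_true(!is.unsorted(tr$t_ms))
})

test_that("branching fixture truth tables are internally consistent", {
  ba <- branching_avalanches(200, sigma = 0.9, bin_ms = 5, seed = 21)
  expect_identical(nrow(ba$truth), 200L)
  expect_identical(sum(ba$truth$size), nrow(ba$events))
  expect_true(all(ba$truth$size >= 1))
  expect_true(all(ba$truth$duration_bins >= 1))
  # gap contract: consecutive avalanches separated by >= gap_bins empty bins
  cat_ <- detect_avalanches(ba$events, bin = 5)
  expect_identical(nrow(cat_), 200L)
})

test_that("subcritical offspring means give mostly short avalanches", {
  ba <- branching_avalanches(500, sigma = 0.3, bin_ms = 5, seed = 22)
  expect_false(any(ba$truth$truncated))
  expect_lt(mean(ba$truth$size), 2)  # mean size 1/(1-sigma) ~ 1.43
  expect_equal(mean(ba$truth$size), 1 / 0.7, tolerance = 0.1)
})

test_that("power-law samples match the target distribution", {
  x <- power_law_samples(5e4, 1.5, seed = 23)
  expect_true(all(x >= 1))
  # exact discrete probabilities from the zeta normalization
  z <- eicrit:::hurwitz_zeta(1.5, 1)
  expect_equal(mean(x == 1), 1 / z, tolerance = 0.02)
  expect_equal(mean(x == 2), 2^-1.5 / z, tolerance = 0.05)
  # determinism
  expect_identical(x, power_law_samples(5e4, 1.5, seed = 23))
})
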