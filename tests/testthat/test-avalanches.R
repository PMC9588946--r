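test_that("avalanche segmentation is exact on a constructed record", {
  # three avalanches in 2 ms bins with known sizes and durations
  ev <- c(0.5, 1.2, 2.1,          # bins 0-1: size 3, duration 2
          10.3,                   # bin 5: size 1, duration 1
          20.1, 20.2, 22.9, 24.5) # bins 10-12: size 4, duration 3
  cat_ <- detect_avalanches(ev, bin = 2)
  expect_identical(cat_$size, c(3L, 1L, 4L))
  expect_identical(cat_$duration_bins, c(2L, 1L, 3L))
  expect_equal(cat_$t_start_ms, c(0, 10, 20))
  expect_equal(attr(cat_, "bin"), 2)
})

test_that("auto binning uses the mean inter-event interval", {
  ev <- c(0, 1, 2, 10)
  cat_ <- detect_avalanches(ev)
  expect_equal(attr(cat_, "bin"), mean(diff(ev)))
})

test_that("Galton-Watson fixture is recovered exactly by the detector", {
  ba <- branching_avalanches(500, sigma = 1, bin_ms = 5, seed = 11)
  cat_ <- detect_avalanches(ba$events, bin = 5)
  expect_identical(nrow(cat_), nrow(ba$truth))
  expect_identical(sort(cat_$size), sort(ba$truth$size))
  expect_identical(sort(cat_$duration_bins), sort(ba$truth$duration_bins))
})

test_that("branching estimators recover the offspring mean", {
  ba1 <- branching_avalanches(3000, sigma = 1, bin_ms = 5, seed = 11)
  s1 <- branching_ratio(ba1$events, method = "bin_ratio", bin = 5)$sigma
  expect_equal(s1, 1, tolerance = 0.05)
  ba8 <- branching_avalanches(3000, sigma = 0.8, bin_ms = 5, seed = 12)
  s8 <- branching_ratio(ba8$events, method = "bin_ratio", bin = 5)$sigma
  expect_equal(s8, 0.8, tolerance = 0.05)
  sc <- branching_ratio(ba1$events, method = "causal", window = 5)$sigma
  expect_equal(sc, 1, tolerance = 0.05)
})

test_that("power-law fitter recovers known exponents (MLE and CCDF)", {
  for (ex in c(1.3, 1.5, 2.0)) {
    x <- power_law_samples(3e4, ex, seed = round(1000 * ex))
    fm <- fit_power_law(x, xmin = 1, method = "mle")
    expect_lt(abs(fm$exponent - ex), 3 * fm$se)
    fc <- fit_power_law(x, method = "ccdf")
    expect_equal(fc$exponent, ex, tolerance = 0.1)
  }
})

test_that("critical branching sizes follow the 3/2 power law", {
  ba <- branching_avalanches(3000, sigma = 1, bin_ms = 5, seed = 11)
  fit <- fit_power_law(detect_avalanches(ba$events, bin = 5)$size,
                       xmin = 1, method = "mle")
  expect_equal(fit$exponent, 1.5, tolerance = 0.05)
})

test_that("ISI statistics of Poisson trains have unit CV", {
  tr <- poisson_train(20, 60000, n_trains = 50, seed = 8)
  cv <- isi_cv(tr, min_spikes = 100)
  expect_equal(cv$cv_mean, 1, tolerance = 0.05)
  expect_identical(cv$n_neurons, 50L)
})

test_that("shape collapse recovers the scaling exponent of synthetic profiles", {
  # construct profiles m_T(s) = T^(gamma-1) * f(s) with known gamma
  gamma_true <- 1.6
  f <- function(s) sin(pi * s)
  durations <- rep(c(5L, 8L, 12L, 16L, 24L), each = 20)
  profs <- lapply(durations, function(Tb) {
    s <- seq(0, 1, length.out = Tb)
    Tb^(gamma_true - 1) * f(s)
  })
  cat_ <- tibble::tibble(id = seq_along(durations),
                         duration_bins = durations,
                         size = vapply(profs, sum, numeric(1)),
                         profile = profs)
  class(cat_) <- c("avalanche_catalog", class(cat_))
  sc <- shape_collapse(cat_, gamma_grid = seq(1.2, 2.2, by = 0.02),
                       min_count = 5)
  expect_equal(sc$gamma, gamma_true, tolerance = 0.05)
})

test_that("size-duration scaling slope is ~2 for the critical fixture", {
  ba <- branching_avalanches(5000, sigma = 1, bin_ms = 5, seed = 13)
  cat_ <- detect_avalanches(ba$events, bin = 5)
  sd_fit <- size_duration_scaling(cat_)
  expect_equal(sd_fit$slope, 2, tolerance = 0.25)
})

test_that("fitters reject degenerate inputs", {
  expect_error(fit_power_law(rep(1, 10)), "too few")
  expect_error(detect_avalanches(numeric(0))$size, NA)
  expect_identical(nrow(detect_avalanches(numeric(0))), 0L)
})
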