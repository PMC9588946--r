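test_that("neuron parameter validation rejects inconsistent potentials", {
  expect_error(neuron_params(v_th = -70), "v_leak")
  expect_error(neuron_params(tau_m = -1))
  p <- neuron_params()
  expect_equal(p$C, p$tau_m * p$g_leak)
})

test_that("peak depolarization is monotone in spike count and weight", {
  peaks <- vapply(1:20, peak_depolarization, numeric(1), w = 0.54)
  expect_true(all(diff(peaks) > 0))
  expect_lt(peak_depolarization(1, 0.54), neuron_params()$v_th)
  expect_gt(peak_depolarization(5, 2), peak_depolarization(5, 1))
})

test_that("default calibration places 0.54 in the 10-20 synchronous-spike band", {
  n <- min_spikes_to_threshold(0.54)
  expect_identical(n, 14L)
  expect_gte(n, 10L)
  expect_lte(n, 20L)
})

test_that("calibrate_weights and calibrate_g0 are mutually consistent", {
  cal <- calibrate_weights(n_target = 14)
  expect_equal(peak_depolarization(14, cal$mean), neuron_params()$v_th,
               tolerance = 1e-6)
  # the frozen default g0 reproduces the dual calibration at w = 0.54
  expect_equal(calibrate_g0(n_target = 14, w_mean = 0.54),
               neuron_params()$g0_exc, tolerance = 1e-6)
  # log-normal moments
  expect_equal(exp(cal$meanlog + cal$sdlog^2 / 2), cal$mean)
})

test_that("closed-form constant-conductance ISI matches brute-force integration", {
  p <- neuron_params()
  g <- 0.8
  T_closed <- lif_isi_constant_g(g, p)
  v <- p$v_rest
  t <- 0
  dt <- 1e-4
  while (v < p$v_th) {
    v <- v + dt * (p$g_leak * (p$v_leak - v) + g * (p$V_R_exc - v)) / p$C
    t <- t + dt
  }
  expect_equal(T_closed, t, tolerance = 1e-3)
  # subthreshold drive never fires
  expect_identical(lif_isi_constant_g(0.1, p), Inf)
})
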