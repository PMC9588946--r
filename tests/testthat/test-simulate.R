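net_cfg <- network_config(n_exc = 200, n_inh = 50, k_EE = 10, k_EI = 3,
                          k_IE = 10, k_II = 3, seed = 61)
net <- build_network(net_cfg)
drv <- drive_params(rho_ext_E = 300, rho_ext_I = 200, w_ext = 0.54)

test_that("simulation is bitwise reproducible under a fixed seed", {
  a <- simulate_network(net, drv, 500, seed = 62)
  b <- simulate_network(net, drv, 500, seed = 62)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$series, b$series)
  expect_identical(a$state, b$state)
})

test_that("an undriven network at rest stays silent", {
  quiet <- simulate_network(net, drive_params(0, 0), 200, seed = 1)
  expect_identical(nrow(quiet$spikes), 0L)
  expect_true(all(abs(quiet$state$v - neuron_params()$v_rest) < 1e-12))
})

test_that("halving dt leaves the population rate nearly unchanged", {
  r1 <- mean(simulate_network(net, drv, 2000, dt = 0.1, seed = 63)$series$rate_E_hz)
  r2 <- mean(simulate_network(net, drv, 2000, dt = 0.05, seed = 63)$series$rate_E_hz)
  expect_gt(r1, 0)
  expect_lt(abs(r1 - r2) / r1, 0.15)
})

test_that("series rates conserve the spike count", {
  sim <- simulate_network(net, drv, 1000, seed = 64, sample_every_ms = 10)
  implied <- sum(sim$series$rate_E_hz * 0.01 * 200 +
                   sim$series$rate_I_hz * 0.01 * 50)
  expect_equal(implied, nrow(sim$spikes), tolerance = 1e-8)
  ps <- population_series(sim$spikes, bin = 20, n_exc = 200, n_inh = 50,
                          t_range = c(0, 1000))
  implied2 <- sum(ps$rate_E_hz * 0.02 * 200 + ps$rate_I_hz * 0.02 * 50)
  expect_equal(implied2, nrow(sim$spikes), tolerance = 1e-8)
})

test_that("resuming from a saved state continues the clock and stays valid", {
  s1 <- simulate_network(net, drv, 300, seed = 65)
  s2 <- simulate_network(net, drv, 300, seed = 66, state = s1$state)
  expect_equal(s2$state$t_ms, 600, tolerance = 1e-9)
  expect_true(all(s2$spikes$t_ms > 300))
  expect_true(all(s2$state$v <= neuron_params()$v_th + 1e-9))
})

test_that("spike records survive a TSV round trip", {
  sim <- simulate_network(net, drv, 200, seed = 67)
  path <- tempfile(fileext = ".tsv")
  write_spikes(sim$spikes, path)
  back <- read_spikes(path)
  expect_equal(back$neuron_id, sim$spikes$neuron_id)
  expect_equal(back$population, sim$spikes$population)
  expect_equal(back$t_ms, sim$spikes$t_ms, tolerance = 1e-9)
  unlink(path)
})

test_that("driven firing is irregular (Poisson-like ISI statistics)", {
  sim <- simulate_network(net, drv, 4000, seed = 68)
  cv <- isi_cv(sim$spikes, min_spikes = 10)
  expect_gt(cv$cv_mean, 0.5)
  expect_lt(cv$cv_mean, 1.5)
})
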