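test_that("the explicit-diffusion stability bound is enforced", {
  expect_error(field_config(nx = 16, dt = 1, dx = 1, D = 1), "stability")
  expect_s3_class(field_config(nx = 16, dt = 0.2, dx = 1, D = 1),
                  "field_config")
})

test_that("the absorbing state is exactly invariant", {
  fc <- field_config(nx = 32, dt = 0.05, D = 1, gamma = 0.5, sigma2 = 1,
                     N_local = 1)
  sim <- simulate_dp_field(fc, E0 = 0, duration = 20, seed = 2)
  expect_identical(max(abs(sim$E)), 0)
})

test_that("point-seeded critical avalanches die and have finite size", {
  fc <- field_config(nx = 32, dt = 0.05, D = 1, gamma = 0, u_quad = 0.02,
                     sigma2 = 1, N_local = 1)
  av <- dp_avalanches(fc, 200, seed_value = 1, max_steps = 2e5, seed = 3)
  expect_true(all(!av$truncated))
  expect_true(all(av$size > 0))
  expect_true(all(av$duration > 0))
})

test_that("subcritical decay and noise-free growth behave analytically", {
  # noise-free homogeneous field: dE/dt = gamma*E - u*E^2 (logistic)
  fc <- field_config(nx = 16, dt = 0.01, D = 1, gamma = 0.5, u_quad = 1,
                     sigma2 = 0, N_local = 1)
  sim <- simulate_dp_field(fc, E0 = 0.1, duration = 40)
  expect_equal(mean(sim$E), 0.5, tolerance = 0.01)
  expect_lt(diff(range(sim$E)), 1e-8)  # spatially homogeneous
})

test_that("normal-form rescaling preserves gamma and matches its algebra", {
  fc <- field_config(nx = 16, dt = 0.05, D = 1, gamma = 0.2, u_quad = 2,
                     sigma2 = 3, N_local = 50)
  rs <- rescale_to_dp(fc)
  expect_equal(rs$gamma, 0.2)
  expect_equal(rs$a, sqrt(3) / sqrt(2 * 50))
  expect_equal(rs$u, sqrt(3) * sqrt(2 / 50))
  # in the normal form, quadratic coefficient equals the noise coefficient
  expect_equal(rs$config$u_quad, rs$u)
  expect_equal(2 * rs$config$sigma2 / rs$config$N_local, 2 * rs$u)
})

test_that("depression-coupled field settles on the predicted intersection", {
  sfp <- stp_field_params(Omega0 = 1.6, alpha_decay = 1, q = 0.01,
                          tau_STP = 50, tau_m = 20)
  st <- stationary_intersection(sfp, u_quad = 1)
  # the intersection solves both stationary branches
  expect_equal(st$E_st, (st$Omega_st - sfp$alpha_decay) / 1, tolerance = 1e-10)
  expect_equal(st$Omega_st, sfp$Omega0 / (1 + sfp$q * sfp$tau_STP * st$E_st),
               tolerance = 1e-10)
  fc <- field_config(nx = 64, dt = 0.05, D = 1, u_quad = 1, sigma2 = 0.01,
                     N_local = 100)
  sim <- simulate_stp_field(fc, sfp, E0 = st$E_st, duration_ms = 4000,
                            sample_every = 20, seed = 31)
  ts <- sim$series[sim$series$t_ms > 1500, ]
  expect_equal(mean(ts$E_mean), st$E_st, tolerance = 0.05)
  expect_equal(mean(ts$Omega_mean), st$Omega_st, tolerance = 0.02)
})

test_that("dispersion relation is gamma - D k^2 for the plain field", {
  fc <- field_config(nx = 16, dt = 0.05, D = 2, gamma = 0.3)
  dr <- dispersion_relation(c(0, 0.5, 1), fc)
  expect_equal(dr$growth_rate, 0.3 - 2 * c(0, 0.25, 1))
  # depression-coupled: homogeneous mode stable at the intersection,
  # large-k modes damped by diffusion
  sfp <- stp_field_params(Omega0 = 1.6, alpha_decay = 1, q = 0.01,
                          tau_STP = 50, tau_m = 20)
  dr2 <- dispersion_relation(c(0, 2), fc, sfp)
  expect_lt(dr2$growth_rate[2], dr2$growth_rate[1])
})
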