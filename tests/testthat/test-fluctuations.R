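mk_cfg <- markov_config(N_E = 200, N_I = 50,
                        coupling = c(c_EE = 0.5, c_EI = -0.3,
                                     c_IE = 0.6, c_II = -0.4),
                        drive = c(E = 10, I = 9.5))

test_that("frozen gain at G reduces to the immigration-death oracle", {
  # exact law: stationary activity G, count variance = count mean
  sim <- simulate_markov(mk_cfg, 2e5, burnin_ms = 1e4, seed = 9,
                         constant_gain = 3)
  expect_equal(sim$mean_e, 3, tolerance = 0.05)
  expect_equal(sim$var_e * mk_cfg$N_E, 3, tolerance = 0.2)
  expect_equal(sim$mean_i, 3, tolerance = 0.1)
})

test_that("deterministic fixed point solves the rate equations", {
  fp <- markov_fixed_point(mk_cfg)
  cc <- mk_cfg$coupling
  zE <- cc[["c_EE"]] * fp[1] + cc[["c_EI"]] * fp[2] + 10
  zI <- cc[["c_IE"]] * fp[1] + cc[["c_II"]] * fp[2] + 9.5
  expect_equal(unname(fp[1]), gain(zE, mk_cfg$gp), tolerance = 1e-6)
  expect_equal(unname(fp[2]), gain(zI, mk_cfg$gp), tolerance = 1e-6)
})

test_that("LNA covariance solves the stationary Lyapunov equation", {
  ln <- lna_variances(mk_cfg)
  expect_true(ln$stable)
  S <- matrix(c(ln$var_e, ln$cov_ei, ln$cov_ei, ln$var_i), 2, 2)
  resid <- ln$A %*% S + S %*% t(ln$A) + ln$B
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("scaled variances grow as the coupling approaches instability", {
  # values stay on the low-activity branch; above ~0.55 the branch is lost
  # and the fixed point jumps to the saturated gain ceiling
  vc <- variance_vs_criticality(mk_cfg, values = c(0.2, 0.35, 0.45, 0.55),
                                knob = "c_EE")
  expect_true(all(vc$stable))
  expect_true(all(diff(vc$scaled_var_e) > 0))
  expect_true(all(diff(vc$distance) < 0))
})

test_that("simulation moments are reproducible and time advances", {
  a <- simulate_markov(mk_cfg, 5e3, seed = 4, sample_n = 50)
  b <- simulate_markov(mk_cfg, 5e3, seed = 4, sample_n = 50)
  expect_identical(a$mean_e, b$mean_e)
  expect_identical(a$path, b$path)
  expect_equal(nrow(a$path), 50)
  expect_gte(a$t_end_ms, 5e3)
})
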