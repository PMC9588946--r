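mf_ref <- meanfield_params(k = c(EE = 20, EI = 5, IE = 20, II = 5),
                           w = c(EE = 0.54, EI = 1.5, IE = 0.75, II = 2),
                           rho_ext_E = 230, rho_ext_I = 150)

test_that("gain is nonnegative, monotone, thresholded and saturating", {
  gp <- gain_params()
  z <- seq(-50, 500, by = 0.5)
  g <- gain(z, gp)
  expect_true(all(g >= 0))
  expect_true(all(diff(g) >= -1e-9))
  expect_equal(gain(-50, gp), 0)
  expect_lt(gain(1e6, gp), gp$rmax)
  expect_gt(gain(1e6, gp), 0.99 * gp$rmax)
})

test_that("mean potentials interpolate between the reversal potentials", {
  v <- average_potential(c(0, 10, 1000), c(0, 10, 1000), mf_ref, "E")
  p <- neuron_params()
  expect_true(all(v > p$V_R_inh & v < p$V_R_exc))
  # zero recurrent rate, zero drive: potential is the leak reversal
  mf0 <- mf_ref
  mf0$rho_ext_E <- 0
  expect_equal(average_potential(0, 0, mf0, "E"), p$v_leak)
  # excitation raises the potential
  expect_gt(average_potential(50, 0, mf_ref, "E"),
            average_potential(0, 0, mf_ref, "E"))
})

test_that("coupling coefficients carry the reversal-potential signs", {
  cc <- coupling_coefficients(mf_ref)
  expect_gt(cc[["c_EE"]], 0)
  expect_gt(cc[["c_IE"]], 0)
  expect_lt(cc[["c_EI"]], 0)
  expect_lt(cc[["c_II"]], 0)
})

test_that("fixed points satisfy the rate equations and attract the ODE flow", {
  fp <- find_fixed_points(mf_ref)
  expect_gt(nrow(fp), 0)
  expect_true(all(fp$residual < 1e-6))
  stable <- fp[grepl("stable", fp$classification) &
                 !grepl("unstable", fp$classification), ]
  expect_gt(nrow(stable), 0)
  traj <- integrate_rate_ode(mf_ref, rho0 = c(1, 1), t_max = 3000)
  final <- unlist(traj[nrow(traj), c("rho_E", "rho_I")])
  d <- sqrt((stable$rho_E - final[1])^2 + (stable$rho_I - final[2])^2)
  expect_lt(min(d), 0.5)
})

test_that("nullcline branches pass through the fixed points", {
  fp <- find_fixed_points(mf_ref)
  pt <- fp[which.max(fp$rho_E), ]
  nc <- nullclines(mf_ref, rho_E_grid = pt$rho_E)
  expect_equal(nc$rho_I_exc_nullcline, pt$rho_I, tolerance = 1e-4)
  expect_equal(nc$rho_I_inh_nullcline, pt$rho_I, tolerance = 1e-4)
})

test_that("BT residuals and the threshold constant are consistent", {
  bt <- bt_residuals(mf_ref)
  expect_true(all(is.finite(c(bt$slope_residual, bt$intercept_residual,
                              bt$deltaW))))
  # deltaW for the reference weights: 0.54*2 - 1.5*0.75
  expect_equal(bt$deltaW, 0.54 * 2 - 1.5 * 0.75)
  # d: unit-weight external rate bringing the mean current to threshold;
  # check against the defining current balance
  p <- neuron_params()
  d <- d_constant(p)
  g_at_d <- p$tau_syn_exc * 1e-3 * p$g0_exc * d
  expect_equal(g_at_d * (p$v_th - p$V_R_exc), p$g_leak * (p$v_rest - p$v_th),
               tolerance = 1e-10)
})

test_that("slow-fast depression layer has the closed-form stationary weight", {
  stp <- stp_params(q = 0.3, tau_STP = 50, w0_EE = 0.54)
  expect_equal(stationary_wEE(0, stp), 0.54)
  expect_equal(stationary_wEE(100, stp), 0.54 / 2.5)
  # the stationary weight zeroes the slow component of the RHS
  rho <- c(20, 15)
  wst <- stationary_wEE(rho[1], stp)
  rhs <- slow_fast_rhs(rho, wst, mf_ref, stp)
  expect_equal(rhs[3], 0, tolerance = 1e-12)
})

test_that("up-down transition conditions respond to depression strength", {
  k <- c(EE = 200, EI = 50)
  out <- up_down_conditions(k, w0_EE = 0.6, w_EI = 1.5, stp_params(q = 0.3),
                            rho_H = 300)
  expect_true(out[["high_state"]])       # 120 > 75 at full resources
  expect_true(out[["depression_escape"]])  # 120/5.5 < 75 when depressed
  out2 <- up_down_conditions(k, w0_EE = 0.3, w_EI = 1.5, stp_params(q = 0.3),
                             rho_H = 300)
  expect_false(out2[["high_state"]])
})
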