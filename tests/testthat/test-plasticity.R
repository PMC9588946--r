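test_that("default kernels satisfy the stability sign conditions", {
  k <- stdp_kernels()
  expect_lt(kernel_integral(k, "E"), 0)  # depression-dominated E kernel
  expect_gt(kernel_integral(k, "I"), 0)  # potentiation-dominated I kernel
  # analytic integral: A+ tau+ - A- tau-
  expect_equal(kernel_integral(k, "E"),
               k$A_plus_E * k$tau_plus_E - k$A_minus_E * k$tau_minus_E)
})

test_that("stationary coupling ratio from kernels is negative", {
  r <- stationary_ratio_from_kernels(stdp_kernels())
  expect_lt(r, 0)
  # the sign guard lives in the constructor itself
  expect_error(stdp_kernels(A_minus_E = 0.001), "negative")
})

test_that("elementary STP updates obey their closed forms", {
  expect_equal(stp_on_pre_spike(1, 0.3), 0.7)
  expect_equal(stp_decay(0.5, 50, 50), 1 - 0.5 * exp(-1))
  expect_equal(effective_weight(0.54, 0.5), 0.27)
  # stationary efficacy: jump-decay balance under Poisson drive
  expect_equal(stp_stationary_efficacy(100, 0.3, 50), 1 / (1 + 1.5))
  expect_equal(stp_stationary_efficacy(0, 0.3, 50), 1)
})

test_that("long-run efficacy under a Poisson train matches the closed form", {
  # drive the jump-decay efficacy process with an actual Poisson train and
  # time-average it exactly between spikes
  tr <- poisson_train(100, 1e6, n_trains = 1, seed = 5)$t_ms
  u <- 1
  q <- 0.3
  tau <- 50
  t_prev <- 0
  int_u <- 0
  for (tt in tr) {
    dt <- tt - t_prev
    int_u <- int_u + dt + (u - 1) * tau * (1 - exp(-dt / tau))
    u <- stp_on_pre_spike(stp_decay(u, dt, tau), q)
    t_prev <- tt
  }
  expect_equal(int_u / t_prev, stp_stationary_efficacy(100, q, tau),
               tolerance = 0.05)
})

test_that("trace-based STDP equals the explicit all-pairs summation", {
  kern <- stdp_kernels(A_plus_E = 1e-4, A_plus_I = 1e-4,
                       w_max_E = 100, w_max_I = 100)  # no clipping
  cfg <- network_config(n_exc = 4, n_inh = 2, k_EE = 2, k_EI = 1,
                        k_IE = 2, k_II = 1,
                        w_mean = c(EE = 0.5, EI = 0.5, IE = 0.5, II = 0.5),
                        cv = 0, seed = 51)
  syn <- build_network(cfg)
  script <- with_seed(52, data.frame(t = sort(runif(400, 0, 1000)),
                                     nrn = sample(1:6, 400, TRUE)))
  tr <- trace_state(4, 2)
  w <- syn$w
  for (si in seq_len(nrow(script))) {
    tr <- trace_decay(tr, script$t[si] - tr$t_ms, kern)
    syn$w <- w
    up <- stdp_on_spike(tr, syn, kern, script$nrn[si], role = "post")
    w[up$edge] <- up$w_new
    syn$w <- w
    up <- stdp_on_spike(tr, syn, kern, script$nrn[si], role = "pre")
    w[up$edge] <- up$w_new
    tr <- trace_bump(tr, script$nrn[si])
  }
  dw_trace <- w - build_network(cfg)$w
  dw_pairs <- vapply(seq_len(nrow(syn)), function(ei) {
    pre_t <- script$t[script$nrn == syn$pre[ei]]
    post_t <- script$t[script$nrn == syn$post[ei]]
    ek <- as.character(syn$class[ei]) %in% c("EE", "IE")
    Ap <- if (ek) kern$A_plus_E else kern$A_plus_I
    Am <- if (ek) kern$A_minus_E else kern$A_minus_I
    tp <- if (ek) kern$tau_plus_E else kern$tau_plus_I
    tm <- if (ek) kern$tau_minus_E else kern$tau_minus_I
    s <- 0
    for (a in pre_t) for (b in post_t) {
      d <- b - a
      s <- s + if (d >= 0) Ap * exp(-d / tp) else -Am * exp(d / tm)
    }
    s
  }, numeric(1))
  expect_lt(max(abs(dw_trace - dw_pairs)), 1e-10)
})

test_that("averaged weight dynamics follow the kernel-integral signs", {
  k <- stdp_kernels()
  rhs <- mean_weight_ode_rhs(c(E = 10, I = 10),
                             c(EE = 0.5, EI = 1.5, IE = 0.75, II = 2),
                             k, correlation_kernel(),
                             vbar = c(E = -60, I = -60))
  expect_true(all(is.finite(rhs)))
  # at zero weights only the rate-product term survives: E-presynaptic
  # classes drift negative, I-presynaptic classes positive
  rhs0 <- mean_weight_ode_rhs(c(E = 10, I = 10),
                              c(EE = 0, EI = 0, IE = 0, II = 0),
                              k, correlation_kernel(),
                              vbar = c(E = -60, I = -60))
  expect_lt(rhs0[["EE"]], 0)
  expect_gt(rhs0[["EI"]], 0)
})
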