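cfg_small <- network_config(n_exc = 100, n_inh = 25, k_EE = 10, k_EI = 5,
                            k_IE = 10, k_II = 5, seed = 7)

test_that("build_network honours exact in-degrees per class", {
  syn <- build_network(cfg_small)
  deg <- table(syn$class, syn$post)
  for (post in 1:100) {
    expect_identical(unname(deg["EE", as.character(post)]), 10L)
    expect_identical(unname(deg["EI", as.character(post)]), 5L)
  }
  for (post in 101:125) {
    expect_identical(unname(deg["IE", as.character(post)]), 10L)
    expect_identical(unname(deg["II", as.character(post)]), 5L)
  }
})

test_that("network wiring has no self-edges and correct id ranges", {
  syn <- build_network(cfg_small)
  expect_true(all(syn$pre != syn$post))
  expect_true(all(syn$pre[syn$class %in% c("EE", "IE")] <= 100))
  expect_true(all(syn$pre[syn$class %in% c("EI", "II")] > 100))
  expect_true(all(syn$post[syn$class %in% c("EE", "EI")] <= 100))
  expect_true(all(syn$post[syn$class %in% c("IE", "II")] > 100))
  # no duplicated edges within a class (sampling without replacement)
  expect_false(any(duplicated(syn[c("pre", "post", "class")])))
})

test_that("weights are positive, clipped, and near the class means", {
  syn <- build_network(cfg_small)
  expect_true(all(syn$w > 0))
  expect_true(all(syn$w[syn$class %in% c("EE", "IE")] <= cfg_small$w_max_E))
  w_ee <- syn$w[syn$class == "EE"]
  expect_equal(mean(w_ee), 0.54, tolerance = 0.05)
  expect_equal(sd(w_ee) / mean(w_ee), 0.2, tolerance = 0.25)
})

test_that("wiring is deterministic under the configuration seed", {
  expect_identical(build_network(cfg_small), build_network(cfg_small))
  cfg2 <- cfg_small
  cfg2$seed <- 8L
  expect_false(identical(build_network(cfg_small)$pre, build_network(cfg2)$pre))
})

test_that("degree bounds are validated", {
  expect_error(network_config(n_exc = 10, n_inh = 2, k_EE = 11), "in-degree")
})

test_that("ring wiring couples populations with distance-decaying weights", {
  cfg <- network_config(n_exc = 40, n_inh = 10, k_EE = 4, k_EI = 2,
                        k_IE = 4, k_II = 2, seed = 3)
  rg <- ring_config(6, cfg, amplitude = 0.1, decay = 2, k_ring = 2)
  syn <- build_ring(rg)
  # pooled sizes: 6*40 E then 6*10 I
  expect_true(all(syn$post >= 1 & syn$post <= 300))
  # cross-population EE edges exist and carry the exponential profile
  pop_of <- function(id) (id - 1) %/% 40 + 1
  ee <- syn[syn$class == "EE" & syn$pre <= 240 & syn$post <= 240, ]
  cross <- ee[pop_of(ee$pre) != pop_of(ee$post), ]
  expect_gt(nrow(cross), 0)
  d <- pmin(abs(pop_of(cross$pre) - pop_of(cross$post)),
            6 - abs(pop_of(cross$pre) - pop_of(cross$post)))
  expect_equal(cross$w, 0.1 * exp(-d / 2), tolerance = 1e-12)
  # nearest neighbours are more strongly coupled than distance-2 ones
  expect_gt(mean(cross$w[d == 1]), mean(cross$w[d == 2]))
})
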