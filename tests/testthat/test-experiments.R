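small_net_cfg <- list(n_exc = 150, n_inh = 40, k_EE = 5, k_EI = 2,
                      k_IE = 5, k_II = 2)

test_that("config validation rejects unknown keys and bad experiments", {
  expect_error(validate_config(list(experiment = "selforg", bogus = 1)),
               "unknown key")
  expect_error(validate_config(list(experiment = "selforg",
                                    network = list(n_exc = 10, typo_key = 2))),
               "typo_key")
  expect_error(validate_config(list(experiment = "nope")), "experiment")
  ok <- validate_config(list(experiment = "avalanche"))
  expect_s3_class(ok, "eicrit_config")
  expect_identical(ok$seed, 1L)
})

test_that("configs survive a YAML round trip", {
  cfg <- list(experiment = "avalanche", seed = 5,
              network = small_net_cfg,
              drive = list(rho_ext_E = 200, rho_ext_I = 150),
              simulation = list(duration_ms = 500))
  path <- tempfile(fileext = ".yaml")
  save_config(cfg, path)
  back <- load_config(path)
  expect_identical(back$experiment, "avalanche")
  # YAML round trip preserves values (integer-vs-double class may change)
  expect_equal(back$network$n_exc, 150)
  expect_equal(back$drive$rho_ext_E, 200)
  unlink(path)
})

test_that("run_experiment writes a self-describing bundle deterministically", {
  cfg <- list(experiment = "avalanche", seed = 11,
              network = small_net_cfg,
              drive = list(rho_ext_E = 300, rho_ext_I = 200),
              simulation = list(duration_ms = 2000))
  d1 <- tempfile()
  d2 <- tempfile()
  run_experiment(cfg, d1)
  run_experiment(cfg, d2)
  for (f in c("series.tsv", "spikes.tsv", "manifest.json", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  # byte-identical numeric tables on re-run with the same seed
  expect_identical(readLines(file.path(d1, "series.tsv")),
                   readLines(file.path(d2, "series.tsv")))
  expect_identical(readLines(file.path(d1, "spikes.tsv")),
                   readLines(file.path(d2, "spikes.tsv")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_identical(man$experiment, "avalanche")
  expect_identical(man$seed, 11L)
  expect_true(nzchar(man$package_version))
  expect_true("series.tsv" %in% unlist(man$files))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the selforg experiment reports the weight balance", {
  cfg <- list(experiment = "selforg", seed = 3,
              network = small_net_cfg,
              drive = list(rho_ext_E = 350, rho_ext_I = 250),
              simulation = list(duration_ms = 1000,
                                record_spikes = FALSE),
              stdp = list(on = TRUE, A_plus_E = 0.1, A_plus_I = 0.1),
              stp = list(on = TRUE))
  d <- tempfile()
  res <- run_experiment(cfg, d)
  expect_true(is.finite(res$summary$deltaW_final))
  expect_true(file.exists(file.path(d, "weights.tsv")))
  unlink(d, recursive = TRUE)
})

test_that("the CLI front end runs an experiment end to end", {
  script <- system.file("scripts", "eicrit", package = "eicrit")
  expect_true(nzchar(script))
  cfg <- list(experiment = "field_dp", seed = 2,
              field = list(nx = 48, dt = 0.05, u_quad = 0.02, sigma2 = 1,
                           N_local = 1, n_avalanches = 300))
  cpath <- tempfile(fileext = ".yaml")
  save_config(cfg, cpath)
  d <- tempfile()
  out <- system2("Rscript", c(script, "run", cpath, "--out", d, "--seed", "7"),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(out, "status"), NULL)  # exit code 0
  expect_true(file.exists(file.path(d, "avalanches.tsv")))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man$seed, 7L)  # --seed overrides the config
  unlink(c(cpath, d), recursive = TRUE)
})
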