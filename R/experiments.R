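eicrit_config_keys <- list(
  top = c("experiment", "seed", "network", "drive", "simulation", "stdp",
          "stp", "ring", "field", "avalanche"),
  network = c("n_exc", "n_inh", "k_EE", "k_EI", "k_IE", "k_II", "w_mean",
              "cv", "seed"),
  drive = c("rho_ext_E", "rho_ext_I", "w_ext"),
  simulation = c("duration_ms", "dt", "sample_every_ms",
                 "weight_sample_every_ms", "record_spikes"),
  stdp = c("on", "A_plus_E", "A_minus_E", "A_plus_I", "A_minus_I",
           "tau_plus", "tau_minus", "w_max_E", "w_max_I"),
  stp = c("on", "q", "tau_STP"),
  ring = c("n_populations", "amplitude", "decay", "k_ring"),
  field = c("nx", "ny", "dx", "dt", "D", "gamma", "u_quad", "sigma2",
            "N_local", "drive", "duration", "n_avalanches", "seed_value"),
  avalanche = c("bin", "xmin", "method"))

check_keys <- function(x, section) {
  allowed <- eicrit_config_keys[[section]]
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    abort(paste0("unknown key(s) in ", section, " section: ",
                 paste(bad, collapse = ", ")))
  invisible(x)
}

#' Read and validate an experiment configuration
#'
#' YAML experiment descriptions with strict key validation: any key not
#' understood by the experiment runner is rejected with an error naming
#' it, so silent misconfiguration (e.g. a typoed parameter falling back
#' to its default) cannot happen. See [run_experiment()] for the
#' recognized experiments and sections.
#'
#' @param path YAML file path.
#' @return A validated list of class `eicrit_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param config Configuration list.
#' @export
validate_config <- function(config) {
  check_keys(config, "top")
  if (is.null(config$experiment) ||
      !config$experiment %in% c("selforg", "avalanche", "updown", "ring",
                                "field_dp"))
    abort("experiment must be one of: selforg, avalanche, updown, ring, field_dp")
  for (s in intersect(names(config), names(eicrit_config_keys)))
    if (s != "top") check_keys(config[[s]], s)
  config$seed <- config$seed %||% 1L
  structure(config, class = "eicrit_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}

cfg_network <- function(config) {
  nw <- config$network %||% list()
  wm <- nw$w_mean
  args <- nw[setdiff(names(nw), "w_mean")]
  if (!is.null(wm)) args$w_mean <- unlist(wm)[c("EE", "EI", "IE", "II")]
  args$seed <- args$seed %||% config$seed
  do.call(network_config, args)
}

cfg_drive <- function(config) do.call(drive_params, config$drive %||% list(rho_ext_E = 150))

cfg_stdp <- function(config) {
  s <- config$stdp
  if (is.null(s) || !isTRUE(s$on)) return(NULL)
  do.call(stdp_kernels, s[setdiff(names(s), "on")])
}

cfg_stp <- function(config) {
  s <- config$stp
  if (is.null(s) || !isTRUE(s$on)) return(NULL)
  do.call(stp_params, s[setdiff(names(s), "on")])
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a configured experiment end to end
#'
#' Executes one of the canned experiment designs and writes its outputs
#' plus a JSON manifest (configuration, seed, package version, time
#' stamps, files written) to `out_dir`:
#' \describe{
#'   \item{`selforg`}{Spiking network with STDP and short-term depression
#'     on; writes the rate/weight series and a summary with the final
#'     weight-balance `deltaW` and rates.}
#'   \item{`avalanche`}{Static network; writes spikes, the avalanche
#'     catalog, and a summary with the size-distribution fit and
#'     branching ratio.}
#'   \item{`updown`}{Static weights with depression only; writes the
#'     rate series and dwell-time summary of high/low episodes.}
#'   \item{`ring`}{Ring of weakly coupled populations; writes spikes and
#'     the pooled series.}
#'   \item{`field_dp`}{Directed-percolation field avalanches; writes the
#'     catalog and the size-distribution fit.}
#' }
#'
#' @param config An `eicrit_config` (or list, validated on entry).
#' @param out_dir Output directory (created if missing).
#' @return The result list (invisibly); side effect: files in `out_dir`.
#' @export
run_experiment <- function(config, out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t_start <- Sys.time()
  sim_args <- config$simulation %||% list()
  duration <- sim_args$duration_ms %||% 10000
  files <- character(0)
  summary <- list(experiment = config$experiment, seed = config$seed)
  res <- list()

  if (config$experiment %in% c("selforg", "avalanche", "updown", "ring")) {
    if (config$experiment == "ring") {
      rg <- do.call(ring_config,
                    c(config$ring %||% list(n_populations = 4),
                      list(config = cfg_network(config))))
      syn <- build_ring(rg)
    } else {
      syn <- build_network(cfg_network(config))
    }
    stdp <- if (config$experiment == "selforg") cfg_stdp(config) else NULL
    stp <- if (config$experiment %in% c("selforg", "updown"))
      cfg_stp(config) %||% stp_params() else cfg_stp(config)
    sim <- simulate_network(
      syn, cfg_drive(config), duration_ms = duration,
      dt = sim_args$dt %||% 0.1, seed = config$seed,
      stdp = stdp, stp = stp,
      sample_every_ms = sim_args$sample_every_ms %||% 10,
      weight_sample_every_ms = sim_args$weight_sample_every_ms %||% 100,
      record_spikes = sim_args$record_spikes %||% TRUE)
    res$sim <- sim
    files <- c(files, write_tsv_plain(sim$series, file.path(out_dir, "series.tsv")))
    if (nrow(sim$spikes))
      files <- c(files, write_spikes(sim$spikes, file.path(out_dir, "spikes.tsv")))
    if (nrow(sim$weights))
      files <- c(files, write_tsv_plain(sim$weights, file.path(out_dir, "weights.tsv")))
    summary$rate_E_hz <- mean(sim$series$rate_E_hz)
    summary$rate_I_hz <- mean(sim$series$rate_I_hz)
    if (config$experiment == "selforg" && nrow(sim$weights)) {
      last <- sim$weights[nrow(sim$weights), ]
      summary$deltaW_final <- last$deltaW
      summary$wEE_eff_final <- last$wEE_eff
    }
    if (config$experiment == "avalanche" && nrow(sim$spikes) > 100) {
      av <- config$avalanche %||% list()
      cat_ <- detect_avalanches(sim$spikes, bin = av$bin %||% "auto")
      res$catalog <- cat_
      files <- c(files, write_tsv_plain(
        cat_[c("id", "t_start_ms", "size", "duration_bins", "duration_ms")],
        file.path(out_dir, "avalanches.tsv")))
      if (nrow(cat_) >= 50) {
        fit <- fit_power_law(cat_, xmin = av$xmin,
                             method = av$method %||% "mle")
        br <- branching_ratio(sim$spikes, bin = av$bin %||% "auto")
        res$fit <- fit
        summary$size_exponent <- fit$exponent
        summary$size_exponent_se <- fit$se
        summary$branching_ratio <- br$sigma
        summary$n_avalanches <- nrow(cat_)
      }
    }
    if (config$experiment == "updown") {
      thr <- stats::median(sim$series$rate_E_hz)
      hi <- sim$series$rate_E_hz > thr
      summary$fraction_high <- mean(hi)
      summary$n_transitions <- sum(diff(hi) != 0)
    }
  } else {  # field_dp
    f <- config$field %||% list()
    fc <- field_config(nx = f$nx %||% 64, ny = f$ny %||% 1,
                       dx = f$dx %||% 1, dt = f$dt %||% 0.1,
                       D = f$D %||% 1, gamma = f$gamma %||% 0,
                       u_quad = f$u_quad %||% 1, sigma2 = f$sigma2 %||% 1,
                       N_local = f$N_local %||% 100, drive = f$drive %||% 0)
    cat_ <- dp_avalanches(fc, n_avalanches = f$n_avalanches %||% 2000,
                          seed_value = f$seed_value %||% 1,
                          seed = config$seed)
    res$catalog <- cat_
    files <- c(files, write_tsv_plain(cat_, file.path(out_dir, "avalanches.tsv")))
    fit <- fit_power_law(pmax(round(cat_$size / stats::median(cat_$size[cat_$size > 0])), 1))
    res$fit <- fit
    summary$size_exponent <- fit$exponent
    summary$n_avalanches <- nrow(cat_)
  }

  manifest <- list(
    experiment = config$experiment,
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("eicrit")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files),
    summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$summary <- summary
  res$manifest <- manifest
  invisible(res)
}
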