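#' Network configuration for the E-I spiking model
#'
#' Sparse random wiring with fixed in-degrees. Every excitatory neuron
#' receives exactly `k_EE` excitatory and `k_EI` inhibitory in-edges; every
#' inhibitory neuron `k_IE` and `k_II`. Synapse classes are labelled
#' post-pre: `EE` (E from E), `EI` (E from I), `IE` (I from E), `II`
#' (I from I). Weights are drawn from a per-class log-normal law with low
#' coefficient of variation and clipped to `(0, w_max]` of their kernel
#' class (`w_max_E` for excitatory presynapses EE/IE, `w_max_I` for EI/II).
#'
#' At full scale the reference system uses `n_exc = 20000`,
#' `n_inh = n_exc/4`, `k_EE = n_exc/100 = 200`, `k_EI = k_II = k_EE/4`,
#' `k_IE = k_EE`; desk-scale runs divide `n_exc` and the degrees jointly
#' and compare rate-level statistics, not absolute counts.
#'
#' @param n_exc,n_inh Population sizes.
#' @param k_EE,k_EI,k_IE,k_II In-degrees by synapse class.
#' @param w_mean Named numeric: mean weight per class
#'   (`EE`, `EI`, `IE`, `II`). Defaults to the reference balanced set
#'   (`EE` 0.54, `EI` 1.5, `IE` 0.75, `II` 2) under the calibrated
#'   conductance scale.
#' @param cv Coefficient of variation of the log-normal weight laws.
#' @param w_max_E,w_max_I Saturation bounds per kernel class; default four
#'   times the initial class mean.
#' @param seed Integer seed making the wiring deterministic.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_exc, n_inh = round(n_exc / 4),
                           k_EE = round(n_exc / 100),
                           k_EI = max(1L, round(k_EE / 4)),
                           k_IE = k_EE, k_II = k_EI,
                           w_mean = c(EE = 0.54, EI = 1.5, IE = 0.75, II = 2),
                           cv = 0.2,
                           w_max_E = 4 * max(w_mean[c("EE", "IE")]),
                           w_max_I = 4 * max(w_mean[c("EI", "II")]),
                           seed = 1L) {
  stopifnot(n_exc >= 1, n_inh >= 0, all(w_mean > 0), cv >= 0)
  ks <- c(k_EE = k_EE, k_EI = k_EI, k_IE = k_IE, k_II = k_II)
  if (k_EE > n_exc || k_IE > n_exc || k_EI > n_inh || k_II > n_inh)
    abort("configuration error: in-degree exceeds source population size")
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 k = ks, w_mean = w_mean[c("EE", "EI", "IE", "II")], cv = cv,
                 w_max_E = w_max_E, w_max_I = w_max_I,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' External Poisson drive parameters
#'
#' Each neuron receives an independent homogeneous Poisson train of
#' excitatory external spikes delivered through the excitatory conductance
#' channel at weight `w_ext` (default: the mean recurrent E-to-E weight).
#'
#' @param rho_ext_E,rho_ext_I Per-neuron external rates (Hz) for the
#'   excitatory and inhibitory populations.
#' @param w_ext Weight of the external synapse.
#' @return A list of class `drive_params`.
#' @export
drive_params <- function(rho_ext_E, rho_ext_I = 150, w_ext = 0.54) {
  stopifnot(rho_ext_E >= 0, rho_ext_I >= 0, w_ext >= 0)
  structure(list(rho_ext_E = rho_ext_E, rho_ext_I = rho_ext_I,
                 w_ext = w_ext), class = "drive_params")
}

lognormal_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

sample_class_edges <- function(posts, n_src, k, exclude_self) {
  # exact in-degree k per post neuron, sources sampled without replacement
  pre <- integer(length(posts) * k)
  for (i in seq_along(posts)) {
    pool <- if (exclude_self) seq_len(n_src)[-posts[i]] else seq_len(n_src)
    pre[((i - 1) * k + 1):(i * k)] <- pool[sample.int(length(pool), k)]
  }
  pre
}

#' Build the synapse table of a sparse E-I network
#'
#' Directed edge list with exact in-degrees per class (see
#' [network_config()]); no self-edges; log-normal weights clipped to
#' `(0, w_max]`. Neuron ids are 1..`n_exc` for excitatory and
#' `n_exc+1`..`n_exc+n_inh` for inhibitory neurons. Deterministic under the
#' configuration seed.
#'
#' @param config A [network_config()] object.
#' @return A tibble of class `synapse_table` with columns `pre`, `post`,
#'   `class` (factor EE/EI/IE/II), `w`; the configuration is attached as
#'   attribute `config`.
#' @export
build_network <- function(config) {
  cfg <- config
  nE <- cfg$n_exc; nI <- cfg$n_inh
  with_seed(cfg$seed, {
    classes <- list(
      EE = list(posts = seq_len(nE), n_src = nE, k = cfg$k[["k_EE"]],
                self = TRUE, off = 0L),
      EI = list(posts = seq_len(nE), n_src = nI, k = cfg$k[["k_EI"]],
                self = FALSE, off = nE),
      IE = list(posts = nE + seq_len(nI), n_src = nE, k = cfg$k[["k_IE"]],
                self = FALSE, off = 0L),
      II = list(posts = nE + seq_len(nI), n_src = nI, k = cfg$k[["k_II"]],
                self = TRUE, off = nE))
    parts <- purrr::imap(classes, function(cl, nm) {
      if (cl$k == 0 || length(cl$posts) == 0 || cl$n_src == 0)
        return(NULL)
      # self-exclusion only applies when source and target populations match
      excl <- cl$self
      posts_local <- if (excl) cl$posts - cl$off else cl$posts
      pre <- sample_class_edges(posts_local, cl$n_src, cl$k, excl) + cl$off
      lp <- lognormal_pars(cfg$w_mean[[nm]], cfg$cv)
      wmax <- if (nm %in% c("EE", "IE")) cfg$w_max_E else cfg$w_max_I
      w <- pmin(rlnorm(length(pre), lp$meanlog, lp$sdlog), wmax)
      tibble::tibble(pre = pre, post = rep(cl$posts, each = cl$k),
                     class = nm, w = w)
    })
    syn <- dplyr::bind_rows(parts)
  })
  if (is.null(syn) || nrow(syn) == 0)
    syn <- tibble::tibble(pre = integer(), post = integer(),
                          class = character(), w = numeric())
  syn$class <- factor(syn$class, levels = c("EE", "EI", "IE", "II"))
  structure(syn, class = c("synapse_table", class(syn)), config = cfg)
}

#' Ring of weakly coupled E-I populations
#'
#' `n_populations` identical E-I populations arranged on a ring. Wiring
#' within each population follows [build_network()]; in addition each
#' excitatory neuron receives `k_ring` E-to-E in-edges from every other
#' population within `3 * decay` ring positions, with weight
#' `amplitude * exp(-ring distance / decay)`. The defaults (amplitude 10%
#' of the intra-population mean EE weight, decay 2 positions) realize weak
#' interconnection that falls off with ring distance.
#'
#' @param n_populations Number of populations on the ring.
#' @param config Per-population [network_config()].
#' @param amplitude Coupling amplitude (weight units).
#' @param decay Decay constant of coupling with ring distance (positions).
#' @param k_ring Cross-population in-degree per source population.
#' @return A list of class `ring_config`.
#' @export
ring_config <- function(n_populations, config,
                        amplitude = 0.1 * config$w_mean[["EE"]],
                        decay = 2, k_ring = max(1L, round(config$k[["k_EE"]] / 10))) {
  stopifnot(n_populations >= 1, amplitude >= 0, decay > 0)
  structure(list(n_populations = as.integer(n_populations), config = config,
                 amplitude = amplitude, decay = decay,
                 k_ring = as.integer(k_ring)),
            class = "ring_config")
}

#' @rdname ring_config
#' @return For `build_ring()`: a `synapse_table` covering all populations.
#'   Excitatory neurons of population `p` occupy ids
#'   `(p-1)*n_exc + 1 .. p*n_exc`; all inhibitory neurons follow after the
#'   `n_populations * n_exc` excitatory block, so the table plugs directly
#'   into [simulate_network()] with the pooled population sizes.
#' @export
build_ring <- function(ring) {
  stopifnot(inherits(ring, "ring_config"))
  cfg <- ring$config
  np <- ring$n_populations
  nE <- cfg$n_exc; nI <- cfg$n_inh
  remap <- function(id, p) {
    ifelse(id <= nE, id + (p - 1L) * nE, np * nE + (p - 1L) * nI + (id - nE))
  }
  parts <- vector("list", np)
  for (p in seq_len(np)) {
    cfg_p <- cfg
    cfg_p$seed <- derive_seed(cfg$seed, paste0("ring", p))
    syn <- build_network(cfg_p)
    syn$pre <- remap(syn$pre, p)
    syn$post <- remap(syn$post, p)
    parts[[p]] <- syn
  }
  cross <- list()
  if (np > 1 && ring$amplitude > 0) {
    with_seed(derive_seed(cfg$seed, "ringx"), {
      for (p in seq_len(np)) for (q in seq_len(np)) {
        if (p == q) next
        d <- min(abs(p - q), np - abs(p - q))
        if (d > 3 * ring$decay) next
        wpq <- ring$amplitude * exp(-d / ring$decay)
        pre <- sample.int(nE, ring$k_ring * nE, replace = TRUE) +
          (q - 1L) * nE
        post <- rep(seq_len(nE), each = ring$k_ring) + (p - 1L) * nE
        cross[[length(cross) + 1L]] <-
          tibble::tibble(pre = pre, post = post, class = "EE",
                         w = rep(wpq, length(pre)))
      }
    })
  }
  syn <- dplyr::bind_rows(c(parts, cross))
  syn$class <- factor(as.character(syn$class), levels = c("EE", "EI", "IE", "II"))
  structure(syn, class = unique(c("synapse_table", class(syn))),
            config = cfg, ring = ring)
}
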