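# Configuration schema, seed policy and run containers (interface module).

#' Derive child seeds from a master seed
#'
#' One master seed spawns independent child seeds for the separate sources
#' of randomness (weights, afferent input, noise, NMF restarts), so changing
#' the number of consumers of one stream never perturbs the others.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

default_config <- function() {
  list(
    neuron = as.list(unclass(neuron_params())),
    receptors = list(
      tau_up = c(0.5, 5.8, 1.8, 1.8, 100),
      tau_dn = c(4.0, 87.5, 12.0, 47.0, 500),
      V_R = c(0, 0, -70, -70, -80),
      g = c(1.05, 1.05, 4.0, 4.0, 2.0)
    ),
    weights = list(
      family = "lognormal",
      sigma_E2 = 1.0
    ),
    network = list(
      N_E = 1000L,
      N_I = NULL,            # defaults to round(N_E / 4)
      gamma_E = 0.1,
      gamma_I = 0.1,
      input_rate = 10,       # Hz, per excitatory neuron
      input_amp = 1300,      # pA, afferent synaptic amplitude
      gate_mode = "saturating",  # per-spike gate events drive s to 1
      gate_charge = 1,       # impulse-mode charge (gate_mode = "impulse")
      tau_input_up = 1,      # ms
      tau_input_dn = 20,     # ms
      tau_axon = 1,          # ms
      dt = 0.05,             # ms
      T_total = 12000,       # ms
      T_transient = 2000,    # ms, discarded from analyses
      noise_sd = 0,          # pA
      seed = 1L,
      trace_n_E = 4L,
      trace_n_I = 2L,
      trace_dt = 1           # ms (1 kHz sampling)
    ),
    detection = list(
      threshold = -62,       # mV, midpoint between DOWN and UP plateaus
      smooth_window = 10,    # ms boxcar
      min_duration = 50,     # ms, both UP and DOWN segments
      merge_gap = 50         # ms
    ),
    nmf = list(
      window = 200,          # ms
      step = 50,             # ms (20 Hz rate-vector sampling)
      k_max = 12L,
      restarts = 3L,
      max_iter = 300L,
      tol = 1e-5
    )
  )
}

merge_validate <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("unknown config key", if (length(extra) > 1) "s" else "", ": ",
         paste0(path, extra, collapse = ", "))
  }
  for (nm in names(user)) {
    defaults[[nm]] <- merge_validate(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "/"))
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration and fills every missing entry from the package
#' defaults (the reference parameter set). Unknown keys are rejected with the
#' offending key named. An empty or missing file yields the full default
#' configuration.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
  }
  cfg <- merge_validate(default_config(), user)
  validate_config(cfg)
}

#' Validate and normalize a configuration list
#'
#' @param cfg a configuration list following the `default_config()` layout.
#' @return the normalized configuration, classed `run_config`.
#' @export
validate_config <- function(cfg) {
  net <- cfg$network
  if (is.null(net$N_I)) cfg$network$N_I <- as.integer(round(net$N_E / 4))
  net <- cfg$network
  stopifnot(net$N_E >= 4, net$N_I >= 1, net$gamma_E > 0, net$gamma_I > 0,
            net$dt > 0, net$T_total > net$T_transient, net$input_rate >= 0)
  # fails early for inadmissible sparse-family variances
  weight_ensemble(cfg$weights$family, cfg$weights$sigma_E2)
  tab <- receptor_table(overrides = cfg$receptors)
  check_receptor_groups(tab)
  stopifnot(cfg$neuron$Delta_T > 0, cfg$neuron$tau_u > 0, cfg$neuron$C > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Build a configuration from arguments
#'
#' Convenience wrapper: any subset of sections can be overridden.
#'
#' @param ... named entries of the `network` section (e.g. `N_E`, `gamma_E`,
#'   `T_total`, `seed`).
#' @param weights optional overrides of the `weights` section.
#' @param neuron,detection,nmf,receptors optional section overrides.
#' @return a `run_config`.
#' @export
network_config <- function(..., weights = list(), neuron = list(),
                           detection = list(), nmf = list(),
                           receptors = list()) {
  user <- list(network = list(...), weights = weights, neuron = neuron,
               detection = detection, nmf = nmf, receptors = receptors)
  user <- user[vapply(user, length, 1L) > 0]
  validate_config(merge_validate(default_config(), user))
}

#' Rescale study conditions to a different network size
#'
#' The mean-field drive scales with the population sizes, so the critical
#' weight-scaling factor goes as \eqn{1/N_E} and the admissible excitatory
#' weight variance as \eqn{\sqrt{N_E}}. This helper maps a configuration to
#' an equivalent one at a different `N_E` using those rules, which makes
#' scaled-down simulations comparable to the reference size.
#'
#' @param cfg a `run_config`.
#' @param N_E_new new excitatory population size.
#' @return rescaled `run_config`.
#' @export
scale_config <- function(cfg, N_E_new) {
  r <- N_E_new / cfg$network$N_E
  cfg$network$gamma_E <- cfg$network$gamma_E / r
  cfg$network$gamma_I <- cfg$network$gamma_I / r
  # the afferent current is gamma_E * input_amp * J * s: compensate the
  # gamma rescaling so the per-neuron afferent drive is size-invariant
  cfg$network$input_amp <- cfg$network$input_amp * r
  cfg$weights$sigma_E2 <- max(cfg$weights$sigma_E2 * sqrt(r), 1e-6)
  cfg$network$N_E <- as.integer(N_E_new)
  cfg$network$N_I <- as.integer(round(N_E_new / 4))
  validate_config(unclass(cfg))
}

#' Write a simulation run to a directory
#'
#' Writes the spike table (`spikes.tsv`), trace table (`traces.tsv`) and the
#' fully resolved configuration (`config.json`) so a run can be re-loaded or
#' inspected with standard tools.
#'
#' @param sim a `network_sim` from [run_simulation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(sim$spikes, file.path(dir, "spikes.tsv"), sep = "\t")
  tr <- data.frame(t_ms = rep(sim$trace_times, times = ncol(sim$traces)),
                   neuron_id = rep(sim$trace_ids, each = nrow(sim$traces)),
                   V_mV = as.numeric(sim$traces))
  data.table::fwrite(tr, file.path(dir, "traces.tsv"), sep = "\t")
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a simulation run written by [write_run()]
#'
#' @param dir run directory.
#' @return a `network_sim`-like list with `spikes`, `traces`, `trace_times`,
#'   `trace_ids` and `config`.
#' @export
read_run <- function(dir) {
  spikes <- as.data.frame(data.table::fread(file.path(dir, "spikes.tsv")))
  tr <- as.data.frame(data.table::fread(file.path(dir, "traces.tsv")))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  ids <- sort(unique(tr$neuron_id))
  times <- sort(unique(tr$t_ms))
  traces <- matrix(NA_real_, nrow = length(times), ncol = length(ids))
  for (k in seq_along(ids)) {
    sub <- tr[tr$neuron_id == ids[k], ]
    traces[, k] <- sub$V_mV[order(sub$t_ms)]
  }
  out <- list(spikes = spikes, traces = traces, trace_times = times,
              trace_ids = ids, config = cfg)
  class(out) <- "network_sim"
  out
}
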