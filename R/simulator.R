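# Network assembly and simulation driver around the compiled integrator.

#' Build a recurrent E/I network
#'
#' Samples the four recurrent weight blocks and the per-E-neuron afferent
#' weights from the configured ensemble, and fixes the receptor table and
#' trace subset. Inhibitory neurons receive no afferent drive.
#'
#' @param config a `run_config` from [network_config()] / [load_config()].
#' @param trace_ids optional integer vector of neuron ids (1..N_E for E,
#'   N_E+1..N_E+N_I for I) whose membrane potential is recorded; defaults to
#'   the first `trace_n_E` excitatory and first `trace_n_I` inhibitory cells.
#' @return object of class `network` holding the weight blocks, receptor
#'   table and configuration.
#' @export
build_network <- function(config, trace_ids = NULL) {
  stopifnot(inherits(config, "run_config"))
  net <- config$network
  W <- sample_weight_matrix(net$N_E, net$N_I, config$weights$family,
                            config$weights$sigma_E2,
                            seed = derive_seeds(net$seed, 2)[1])
  if (is.null(trace_ids)) {
    trace_ids <- c(seq_len(min(net$trace_n_E, net$N_E)),
                   net$N_E + seq_len(min(net$trace_n_I, net$N_I)))
  }
  tab <- check_receptor_groups(receptor_table(overrides = config$receptors))
  out <- list(JE = rbind(W$EE, W$IE), JI = rbind(W$EI, W$II),
              J_input = W$input, receptors = tab, trace_ids = trace_ids,
              config = config)
  class(out) <- "network"
  out
}

#' @export
print.network <- function(x, ...) {
  net <- x$config$network
  cat(sprintf("recurrent network: N_E = %d, N_I = %d, %s weights (sigma_E2 = %g)\n",
              net$N_E, net$N_I, x$config$weights$family,
              x$config$weights$sigma_E2))
  cat(sprintf("  gamma_E = %g, gamma_I = %g, afferent %g Hz per E cell\n",
              net$gamma_E, net$gamma_I, net$input_rate))
  invisible(x)
}

#' Generate afferent Poisson event lists
#'
#' Independent homogeneous Poisson spike trains, one per excitatory neuron,
#' at the configured rate. This is the reference event generator used in
#' tests; the compiled simulator draws an identically distributed stream
#' internally.
#'
#' @param config a `run_config`.
#' @param duration duration (ms).
#' @param seed integer seed.
#' @return list of numeric vectors of spike times (ms), one per E neuron.
#' @export
generate_afferent <- function(config, duration, seed = 1) {
  rate <- config$network$input_rate
  if (rate < 0) stop("afferent rate must be non-negative")
  set.seed(seed)
  lapply(seq_len(config$network$N_E), function(i) {
    n <- rpois(1, rate * duration / 1000)
    sort(runif(n, 0, duration))
  })
}

#' Run a network simulation
#'
#' Integrates all membrane, adaptation and gating variables with a shared
#' second-order Runge-Kutta step, delivering recurrent spikes with a 1 ms
#' axonal delay and driving each excitatory neuron with an independent
#' Poisson afferent train. The full spike raster and the membrane traces of
#' the configured subset are recorded; the initial transient
#' (`T_transient`, default 2 s) is kept in the raw output but flagged so
#' analyses can discard it.
#'
#' @param network a `network` from [build_network()], or a `run_config`
#'   (a network is then built from it).
#' @return object of class `network_sim` with elements `spikes`
#'   (data.frame: `neuron_id`, `type`, `t_ms`), `traces` (time x neuron
#'   matrix, mV), `trace_times` (ms), `trace_ids`, `config`, `elapsed`
#'   (seconds of wall time).
#' @export
run_simulation <- function(network) {
  if (inherits(network, "run_config")) network <- build_network(network)
  stopifnot(inherits(network, "network"))
  cfg <- network$config
  net <- cfg$network
  set.seed(derive_seeds(net$seed, 2)[2])
  t0 <- proc.time()["elapsed"]
  res <- run_network_cpp(cfg$neuron, network$JE, network$JI,
                         network$J_input, as.list(network$receptors),
                         net$gamma_E, net$gamma_I,
                         net$input_rate, net$input_amp,
                         net$tau_input_up, net$tau_input_dn,
                         net$tau_axon, net$noise_sd,
                         net$gate_mode == "saturating", net$gate_charge,
                         net$T_total, net$dt,
                         as.integer(network$trace_ids), net$trace_dt)
  elapsed <- unname(proc.time()["elapsed"] - t0)
  type <- ifelse(res$spike_id <= net$N_E, "E", "I")
  ord <- order(res$spike_t, res$spike_id)
  spikes <- data.frame(neuron_id = res$spike_id[ord], type = type[ord],
                       t_ms = res$spike_t[ord])
  out <- list(spikes = spikes, traces = res$traces,
              trace_times = res$trace_times, trace_ids = network$trace_ids,
              config = cfg, elapsed = elapsed)
  class(out) <- "network_sim"
  out
}

#' Spikes after the analysis transient
#'
#' @param sim a `network_sim`.
#' @param type optional `"E"` or `"I"` filter.
#' @return spike data.frame restricted to `t_ms >= T_transient`.
#' @export
analysis_spikes <- function(sim, type = NULL) {
  sp <- sim$spikes[sim$spikes$t_ms >= sim$config$network$T_transient, ,
                   drop = FALSE]
  if (!is.null(type)) sp <- sp[sp$type == type, , drop = FALSE]
  sp
}

#' @export
print.network_sim <- function(x, ...) {
  net <- x$config$network
  sp <- analysis_spikes(x)
  dur_s <- (net$T_total - net$T_transient) / 1000
  rE <- sum(sp$type == "E") / net$N_E / dur_s
  rI <- sum(sp$type == "I") / net$N_I / dur_s
  cat(sprintf("network simulation: %g s (+%g s transient), N_E = %d, N_I = %d\n",
              dur_s, net$T_transient / 1000, net$N_E, net$N_I))
  cat(sprintf("  %d spikes after transient; mean rate E %.2f Hz, I %.2f Hz\n",
              nrow(sp), rE, rI))
  cat(sprintf("  traces: %d neurons at %g kHz; elapsed %.1f s\n",
              length(x$trace_ids), 1 / net$trace_dt, x$elapsed))
  invisible(x)
}

#' Raster and trace display of a simulation
#'
#' @param x a `network_sim`.
#' @param trace index (into `trace_ids`) of the membrane trace shown in the
#'   lower panel.
#' @param ... passed to `plot`.
#' @export
plot.network_sim <- function(x, trace = 1, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  sp <- x$spikes
  plot(sp$t_ms / 1000, sp$neuron_id, pch = ".", col = ifelse(sp$type == "E",
       "black", "red"), xlab = "time (s)", ylab = "neuron", ...)
  plot(x$trace_times / 1000, x$traces[, trace], type = "l",
       xlab = "time (s)", ylab = "V (mV)")
  invisible(x)
}
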