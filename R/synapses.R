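# Five-receptor synaptic kinetics: receptor table, single-gate simulation,
# analytic mean gating under Poisson drive, and synaptic-current assembly.

#' Receptor kinetic table
#'
#' Kinetic constants, reversal potentials and conductances of the five
#' receptor classes mediating recurrent synaptic currents. AMPA and NMDA are
#' carried by excitatory presynaptic neurons; the two GABA-A components and
#' GABA-B by inhibitory ones. Each excitatory connection drives its AMPA and
#' NMDA gates with the same weight, each inhibitory connection its three GABA
#' gates; the slow GABA-A component shares the GABA-A conductance.
#'
#' @param overrides optional named list of column overrides, each a length-5
#'   vector in receptor order (AMPA, NMDA, GABA_A_fast, GABA_A_slow, GABA_B).
#' @return data.frame with columns `name`, `tau_up` (ms), `tau_dn` (ms),
#'   `V_R` (mV), `g` (nS), `carrier`.
#' @export
receptor_table <- function(overrides = NULL) {
  tab <- data.frame(
    name = c("AMPA", "NMDA", "GABA_A_fast", "GABA_A_slow", "GABA_B"),
    tau_up = c(0.5, 5.8, 1.8, 1.8, 100),
    tau_dn = c(4.0, 87.5, 12.0, 47.0, 500),
    V_R = c(0, 0, -70, -70, -80),
    g = c(1.05, 1.05, 4.0, 4.0, 2.0),
    carrier = c("excitatory", "excitatory", "inhibitory", "inhibitory",
                "inhibitory"),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% c("tau_up", "tau_dn", "V_R", "g")) {
        stop("unknown receptor column override: ", nm)
      }
      v <- overrides[[nm]]
      if (length(v) != 5) stop("receptor override '", nm, "' must have length 5")
      tab[[nm]] <- as.numeric(v)
    }
  }
  stopifnot(all(tab$tau_up > 0), all(tab$tau_dn > 0), all(tab$g >= 0))
  tab
}

# the compiled network loop merges receptors sharing V_R and g within each
# carrier group; reject tables that break that assumption
check_receptor_groups <- function(tab) {
  if (tab$V_R[1] != tab$V_R[2]) {
    stop("AMPA and NMDA must share a reversal potential")
  }
  if (tab$V_R[3] != tab$V_R[4] || tab$g[3] != tab$g[4]) {
    stop("fast and slow GABA-A must share reversal potential and conductance")
  }
  invisible(tab)
}

#' Simulate a single synaptic gate
#'
#' Integrates the second-order gating kinetics
#' \eqn{\dot x = -x/\tau_{up} + (1/\tau_{up})\sum\delta(t - t^{sp} - \tau_{axon})},
#' \eqn{\dot s = x(1-s) - s/\tau_{dn}} for one receptor driven by a
#' presynaptic spike train.
#'
#' @param spec one row of [receptor_table()], or a list with `tau_up`,
#'   `tau_dn`.
#' @param presyn_spikes presynaptic spike times (ms), un-delayed.
#' @param T simulated duration (ms).
#' @param dt step (ms).
#' @param tau_axon axonal delay (ms) added to each spike time.
#' @param mode `"saturating"` (default): each delivered spike sets the gate
#'   to 1, which under Poisson drive reproduces the analytic stationary mean
#'   \eqn{\tau_{dn} f_0/(1+\tau_{dn} f_0)} exactly at every rate.
#'   `"impulse"`: the rise variable receives a unit-area impulse
#'   `kick`/\eqn{\tau_{up}}; its stationary mean falls short of the
#'   analytic curve by up to ~30 percent because a single impulse only
#'   drives the gate to \eqn{1 - e^{-kick}} of saturation.
#' @param kick impulse-mode charge (dimensionless, default 1).
#' @param keep_trace return the full `s(t)` trace.
#' @return list with `mean_s`, `min_s`, `max_s` and (optionally) `s` sampled
#'   each step.
#' @export
simulate_gating <- function(spec, presyn_spikes, T, dt = 0.05,
                            tau_axon = 1, mode = c("saturating", "impulse"),
                            kick = 1, keep_trace = FALSE) {
  mode <- match.arg(mode)
  stopifnot(T > 0, dt > 0, kick > 0)
  res <- simulate_gating_cpp(spec$tau_up, spec$tau_dn,
                             sort(presyn_spikes) + tau_axon, T, dt,
                             keep_trace, kick, mode == "saturating")
  if (res$min_s < -1e-8 || res$max_s > 1 + 1e-8) {
    stop("integration failure: gating variable left [0, 1]")
  }
  res
}

#' Analytic mean gating under stationary presynaptic firing
#'
#' Time average of the gating variable when the presynaptic neuron fires at
#' a stationary rate \eqn{f_0}:
#' \eqn{\langle s\rangle = \tau_{dn} f_0 / (1 + \tau_{dn} f_0)} (with
#' \eqn{\tau_{dn}} in seconds for \eqn{f_0} in Hz).
#'
#' @param f0 presynaptic firing rate (Hz), >= 0.
#' @param spec receptor spec with `tau_dn` in ms.
#' @return mean gating (dimensionless, in `[0, 1)`).
#' @export
mean_gating <- function(f0, spec) {
  if (any(f0 < 0)) stop("presynaptic rate must be non-negative")
  tf <- (spec$tau_dn / 1000) * f0
  tf / (1 + tf)
}

#' Assemble the synaptic current onto one postsynaptic neuron
#'
#' Conductance-based current
#' \eqn{I = \gamma_E \sum_{\psi \in exc}\sum_j J_j g_\psi s_{\psi,j}(V_{R,\psi}-V)
#'        + \gamma_I \sum_{\psi \in inh}\sum_k J_k g_\psi s_{\psi,k}(V_{R,\psi}-V)},
#' using the postsynaptic cell's own membrane potential in every driving
#' force. Used directly in tests and by the mean-field module; the network
#' simulator evaluates the identical sum in compiled code.
#'
#' @param postsyn_V postsynaptic membrane potential (mV).
#' @param gating named list of gating vectors, one per receptor name of
#'   [receptor_table()]; excitatory receptors indexed by presynaptic E
#'   neuron, inhibitory ones by presynaptic I neuron.
#' @param weights_E weight row for excitatory presynaptic neurons
#'   (length = length of the excitatory gating vectors).
#' @param weights_I weight row for inhibitory presynaptic neurons.
#' @param gamma_E,gamma_I weight scaling factors.
#' @param receptors receptor table.
#' @return current (pA).
#' @export
synaptic_current <- function(postsyn_V, gating, weights_E, weights_I,
                             gamma_E, gamma_I, receptors = receptor_table()) {
  I <- 0
  for (r in seq_len(nrow(receptors))) {
    nm <- receptors$name[r]
    s <- gating[[nm]]
    if (is.null(s)) stop("gating for receptor ", nm, " missing")
    exc <- receptors$carrier[r] == "excitatory"
    w <- if (exc) weights_E else weights_I
    if (length(s) != length(w)) {
      stop("gating/weight length mismatch for receptor ", nm)
    }
    gam <- if (exc) gamma_E else gamma_I
    I <- I + gam * receptors$g[r] * (receptors$V_R[r] - postsyn_V) *
      sum(w * s)
  }
  I
}
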