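# shared helpers for the test suite

# small, fast neuron simulations
no_sfa <- neuron_params(a_u = 0, b_u = 0)

# cached quartic response fit on a coarse grid (used by several files)
cached_fi_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fi <- measure_fi_curve(currents = seq(0, 1970, by = 80),
                             sim_time = 2000, discard = 500)
      fit <<- fit_response_function(fi, params = no_sfa)
    }
    fit
  }
})

# printed reference coefficients of the quartic response function
reference_fit <- function() {
  fi_fit(theta_f = 130, A = 1.32, B = -1.47e-3, Ccoef = 7.86e-7,
         D = -1.56e-10)
}

# a small transient-regime simulation shared across test files
cached_small_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      cfg <- network_config(N_E = 250, gamma_E = 0.4, gamma_I = 0.4,
                            T_total = 8000, seed = 42, trace_n_E = 16L,
                            trace_n_I = 2L, weights = list(sigma_E2 = 1))
      sim <<- run_simulation(cfg)
    }
    sim
  }
})
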