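# single-neuron dynamics, f-I curve and response-function fit

test_that("leak reversal is the rest point with zero input and no adaptation", {
  p <- neuron_params()
  st <- neuron_state(params = p)
  for (k in 0:99) {
    st <- step_neuron(st, p, I_total = 0, t = k * 0.05, dt = 0.05)$state
  }
  # the spike-generation term contributes ~0.01 pA at rest, so the fixed
  # point sits a fraction of a millivolt above V_L
  expect_lt(abs(st$V - p$V_L), 0.01)
  expect_lt(abs(st$u), 0.001)
})

test_that("R step_neuron and the compiled integrator agree on a trajectory", {
  p <- neuron_params()
  dt <- 0.05
  spikes_cpp <- upstates:::simulate_neuron_cpp(unclass(p), 300, 200, dt)
  st <- neuron_state(params = p)
  spikes_r <- numeric(0)
  for (k in seq_len(200 / dt) - 1) {
    out <- step_neuron(st, p, 300, k * dt, dt)
    st <- out$state
    if (out$spike) spikes_r <- c(spikes_r, st$t_last_spike)
  }
  expect_equal(spikes_r, spikes_cpp, tolerance = 1e-10)
})

test_that("spike-frequency adaptation slows firing from onset to steady state", {
  tr <- simulate_neuron(neuron_params(), I = 300, sim_time = 2000)
  isi <- diff(tr$spike_times)
  expect_gt(length(isi), 3)
  # instantaneous rate declines: first interval much shorter than the last
  expect_lt(isi[1], 0.5 * tail(isi, 1))
  # and the steady rate is below the no-SFA rate at the same current
  n_nosfa <- length(upstates:::simulate_neuron_cpp(unclass(no_sfa), 300,
                                                   2000, 0.05))
  expect_lt(length(tr$spike_times), n_nosfa)
})

test_that("no two spikes occur within the 2 ms refractory period", {
  for (I in c(500, 1900, 5000)) {
    st <- upstates:::simulate_neuron_cpp(unclass(no_sfa), I, 500, 0.05)
    expect_gte(min(diff(st)), 2)
  }
})

test_that("without adaptation, suprathreshold firing is periodic", {
  st <- upstates:::simulate_neuron_cpp(unclass(no_sfa), 400, 2000, 0.05)
  isi <- diff(st)
  isi <- isi[-(1:3)]
  expect_lt(diff(range(isi)), 0.06)  # constant to about one time step
})

test_that("steady firing rate converges under dt halving", {
  r <- vapply(c(0.05, 0.025), function(dt) {
    length(upstates:::simulate_neuron_cpp(unclass(no_sfa), 500, 2000, dt))
  }, numeric(1))
  expect_lt(abs(r[1] - r[2]) / r[2], 0.02)
})

test_that("f-I curve: silent below rheobase, type-I onset, SFA suppression", {
  fi <- measure_fi_curve(currents = c(100, 135, 200, 400), sim_time = 2000,
                         discard = 500)
  expect_equal(fi$rate[1], 0)            # 100 pA is below threshold
  expect_gt(fi$rate[2], 0)               # just above: low but positive
  expect_lt(fi$rate[2], 25)              # continuous (type-I) onset
  expect_true(all(diff(fi$rate) > 0))    # monotone without SFA
  fiS <- measure_fi_curve(params = neuron_params(),
                          currents = c(200, 400), sim_time = 2000,
                          discard = 500)
  expect_true(all(fiS$rate < fi$rate[3:4]))
  expect_error(measure_fi_curve(currents = 100, sim_time = 0), "sim_time")
})

test_that("rheobase by bisection is near 130 pA and matches the grid", {
  rb <- find_rheobase(tol = 0.5, sim_time = 2000, discard = 500)
  expect_equal(rb, 130, tolerance = 5 / 130)
  fi <- measure_fi_curve(currents = seq(100, 160, by = 10), sim_time = 2000,
                         discard = 500)
  grid_est <- max(fi$current[fi$rate == 0])
  expect_lte(abs(rb - grid_est), 10)  # within one grid step
})

test_that("quartic fit recovers the response-function coefficients", {
  fit <- cached_fi_fit()
  expect_equal(fit$theta_f, 130, tolerance = 5 / 130)
  expect_equal(unname(fit$coef["A"]), 1.32, tolerance = 0.1)
  # sign pattern of the printed coefficients
  expect_lt(fit$coef["B"], 0)
  expect_gt(fit$coef["Ccoef"], 0)
  expect_lt(fit$coef["D"], 0)
  # gated through the origin
  expect_equal(unname(predict(fit, fit$theta_f)), 0)
  expect_equal(unname(predict(fit, fit$theta_f - 50)), 0)
})

test_that("evaluating the printed quartic reproduces hand arithmetic", {
  fit <- reference_fit()
  x <- 170
  by_hand <- 1.32 * x - 1.47e-3 * x^2 + 7.86e-7 * x^3 - 1.56e-10 * x^4
  expect_equal(unname(predict(fit, 130 + 170)), by_hand)
  expect_equal(by_hand, 185.648, tolerance = 1e-3)
})

test_that("degenerate f-I input is rejected", {
  expect_error(fit_response_function(data.frame(current = 1:5,
                                                rate = rep(0, 5))),
               "no rheobase")
})
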