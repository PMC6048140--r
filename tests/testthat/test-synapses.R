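# synaptic gating kinetics and current assembly

test_that("receptor table defaults and group structure are consistent", {
  tab <- receptor_table()
  expect_equal(tab$tau_up, c(0.5, 5.8, 1.8, 1.8, 100))
  expect_equal(tab$tau_dn, c(4.0, 87.5, 12.0, 47.0, 500))
  expect_equal(tab$V_R, c(0, 0, -70, -70, -80))
  expect_equal(tab$g, c(1.05, 1.05, 4.0, 4.0, 2.0))
  expect_error(receptor_table(overrides = list(bogus = 1:5)), "unknown")
  bad <- receptor_table()
  bad$g[4] <- 1
  expect_error(upstates:::check_receptor_groups(bad), "GABA-A")
})

test_that("a silent synapse stays closed and a single spike decays with tau_dn", {
  tab <- receptor_table()
  quiet <- simulate_gating(tab[1, ], numeric(0), T = 100)
  expect_equal(quiet$mean_s, 0)
  one <- simulate_gating(tab[1, ], 5, T = 400, keep_trace = TRUE)
  s <- one$s
  expect_gt(max(s), 0)
  ipk <- which.max(s)
  # monotone decay after the peak, with time constant ~ tau_dn = 4 ms:
  # value 4 ms past the peak is ~ exp(-1) of the peak
  dt <- 0.05
  ratio <- s[ipk + round(4 / dt)] / s[ipk]
  expect_equal(ratio, exp(-1), tolerance = 0.15)
  expect_lt(s[ipk + round(40 / dt)], 0.01 * s[ipk])
})

test_that("gating stays in [0, 1] under strong drive", {
  tab <- receptor_table()
  res <- simulate_gating(tab[5, ], seq(1, 2000, by = 2), T = 2500,
                         keep_trace = TRUE)
  expect_gte(res$min_s, 0)
  expect_lte(res$max_s, 1)
  expect_gt(res$max_s, 0.9)  # 500 Hz drive saturates the slow gate
})

test_that("mean gating follows tau_dn f / (1 + tau_dn f)", {
  tab <- receptor_table()
  expect_equal(mean_gating(0, tab[1, ]), 0)
  expect_equal(mean_gating(1e9, tab[1, ]), 1, tolerance = 1e-3)
  expect_equal(mean_gating(50, tab[1, ]), 0.2 / 1.2, tolerance = 1e-12)
  gb <- tab[tab$name == "GABA_B", ]
  expect_equal(mean_gating(10, gb), (0.5 * 10) / (1 + 0.5 * 10))
  expect_error(mean_gating(-1, tab[1, ]), "non-negative")
})

test_that("simulated Poisson time-averaged gating matches the analytic mean", {
  # GABA-B at 10 Hz: <s> = 5/6; moderate duration keeps the check fast
  tab <- receptor_table()
  gb <- tab[tab$name == "GABA_B", ]
  set.seed(11)
  spikes <- cumsum(rexp(600, rate = 10 / 1000))
  res <- simulate_gating(gb, spikes, T = max(spikes), dt = 0.1)
  expect_equal(res$mean_s, 0.8333, tolerance = 0.05)
})

test_that("synaptic current: closed channels, reversal nulls, superposition", {
  tab <- receptor_table()
  n_E <- 5; n_I <- 3
  gat0 <- list(AMPA = rep(0, n_E), NMDA = rep(0, n_E),
               GABA_A_fast = rep(0, n_I), GABA_A_slow = rep(0, n_I),
               GABA_B = rep(0, n_I))
  wE <- rep(1, n_E); wI <- rep(1, n_I)
  expect_equal(synaptic_current(-60, gat0, wE, wI, 0.1, 0.1), 0)
  gat <- lapply(gat0, function(v) v + 0.3)
  # at V = 0 the excitatory driving force vanishes; only GABA remains
  I0 <- synaptic_current(0, gat, wE, wI, 0.1, 0.1)
  Ie_only <- synaptic_current(0, gat, wE, wI, 0.1, 0)
  expect_equal(Ie_only, 0)
  expect_lt(I0, 0)
  # at V = -70 GABA-A is nulled but GABA-B still hyperpolarizes
  Ii_only <- synaptic_current(-70, gat, wE, wI, 0, 0.1)
  gb_expect <- 0.1 * 2.0 * (-80 - (-70)) * sum(wI * 0.3)
  expect_equal(Ii_only, gb_expect)
  # linear in gamma_E and gamma_I separately (superposition on frozen gating)
  V <- -60
  I_full <- synaptic_current(V, gat, wE, wI, 0.2, 0.3)
  I_E <- synaptic_current(V, gat, wE, wI, 0.2, 0)
  I_I <- synaptic_current(V, gat, wE, wI, 0, 0.3)
  expect_equal(I_full, I_E + I_I)
  expect_equal(synaptic_current(V, gat, wE, wI, 0.4, 0), 2 * I_E)
  expect_error(synaptic_current(V, gat, wE[-1], wI, 0.1, 0.1), "mismatch")
})
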