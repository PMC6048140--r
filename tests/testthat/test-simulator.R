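# network assembly and simulation invariants (small networks keep this fast)

tiny_cfg <- function(...) {
  args <- modifyList(list(N_E = 40, gamma_E = 2.5, gamma_I = 2.5,
                          T_total = 2500, seed = 13L, trace_n_E = 4L,
                          trace_n_I = 2L), list(...))
  do.call(network_config, c(args, list(weights = list(sigma_E2 = 1))))
}

test_that("network construction honors sizes and afferent wiring", {
  cfg <- network_config(N_E = 1000)
  expect_equal(cfg$network$N_I, 250L)  # N_I = N_E / 4
  net <- build_network(tiny_cfg())
  expect_equal(dim(net$JE), c(50, 40))
  expect_equal(dim(net$JI), c(50, 10))
  expect_equal(length(net$J_input), 40)  # E cells only receive input
  # determinism of construction
  net2 <- build_network(tiny_cfg())
  expect_identical(net$JE, net2$JE)
})

test_that("afferent Poisson counts match their law", {
  cfg <- tiny_cfg()
  ev <- generate_afferent(cfg, duration = 1e5, seed = 21)
  counts <- lengths(ev)
  # rate 10 Hz over 100 s: mean 1000, sd ~ sqrt(1000)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / length(counts)))
  expect_true(all(counts > 1000 - 5 * sqrt(1000) &
                  counts < 1000 + 5 * sqrt(1000)))
  cfg$network$input_rate <- -1
  expect_error(generate_afferent(cfg, 100), "non-negative")
})

test_that("identical config and seed reproduce the raster bit-for-bit", {
  s1 <- run_simulation(tiny_cfg())
  s2 <- run_simulation(tiny_cfg())
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$traces, s2$traces)
  s3 <- run_simulation(tiny_cfg(seed = 14L))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("no neuron fires twice within the refractory period", {
  sim <- cached_small_sim()
  byn <- split(sim$spikes$t_ms, sim$spikes$neuron_id)
  gaps <- unlist(lapply(byn, function(tt) if (length(tt) > 1) diff(tt)))
  expect_gte(min(gaps), 2)
  expect_true(all(sim$spikes$t_ms >= 0 &
                  sim$spikes$t_ms < sim$config$network$T_total))
})

test_that("without afferent drive the network rests near the leak reversal", {
  cfg <- tiny_cfg(input_rate = 0, T_total = 1200, T_transient = 200)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$spikes), 0)
  late <- sim$traces[sim$trace_times > 500, ]
  expect_true(all(abs(late - (-70)) < 0.5))
})

test_that("DOWN-state membrane sits in a band near the leak/GABA-A reversal", {
  sim <- cached_small_sim()
  v <- as.numeric(sim$traces[sim$trace_times >=
                               sim$config$network$T_transient, ])
  down_level <- quantile(v, 0.2)  # DOWN plateau, below UP excursions
  expect_gt(down_level, -85)
  expect_lt(down_level, -62)
})

test_that("population rate is stable under dt halving", {
  r <- vapply(c(0.05, 0.025), function(dt) {
    cfg <- tiny_cfg(dt = dt, T_total = 4000)
    nrow(analysis_spikes(run_simulation(cfg), "E"))
  }, numeric(1))
  expect_lt(abs(r[1] - r[2]) / max(r[2], 1), 0.25)
})

test_that("simulations feed the analysis chain end to end", {
  sim <- cached_small_sim()
  seg <- segment_updown(sim)
  expect_s3_class(seg, "updown_seg")
  cs <- cycle_statistics(seg)
  expect_gt(cs$n_cycles, 0)
  expect_equal(mean(cs$normalized), 1, tolerance = 1e-9)
  sp <- analysis_spikes(sim, "E")
  expect_true(all(sp$neuron_id <= sim$config$network$N_E))
})
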