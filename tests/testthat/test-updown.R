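# UP/DOWN segmentation, cycle statistics, Fano factors

test_that("square-wave traces are segmented exactly", {
  win <- cbind(c(500, 1500, 2500), c(1000, 2000, 3000))
  tr <- make_square_trace(win, T = 3500, dt = 1)
  seg <- segment_updown(tr$V, tr$times)
  iv <- seg$intervals[[1]]
  expect_equal(nrow(iv), 3)
  expect_equal(iv$offset - iv$onset, rep(500, 3), tolerance = 0.03)
  expect_equal(iv$onset, win[, 1], tolerance = 6)
})

test_that("a constant DOWN trace yields no UP intervals", {
  seg <- segment_updown(rep(-70, 2000), seq_len(2000))
  expect_equal(nrow(seg$intervals[[1]]), 0)
  cs <- cycle_statistics(seg)
  expect_equal(cs$n_cycles, 0)  # empty-stats marker, no error
})

test_that("segmentation enforces the minimum duration and merge gap", {
  # 30 ms blip is dropped; 40 ms gap between UPs is merged
  win <- cbind(c(200, 600, 840), c(230, 800, 1100))
  tr <- make_square_trace(win, T = 1400, dt = 1)
  seg <- segment_updown(tr$V, tr$times)
  iv <- seg$intervals[[1]]
  expect_equal(nrow(iv), 1)
  expect_equal(iv$offset - iv$onset, 500, tolerance = 15)
})

test_that("segmentation is idempotent under integer upsampling", {
  win <- cbind(c(300, 1200), c(800, 1900))
  tr1 <- make_square_trace(win, T = 2400, dt = 2)
  tr2 <- make_square_trace(win, T = 2400, dt = 1)
  s1 <- segment_updown(tr1$V, tr1$times)$intervals[[1]]
  s2 <- segment_updown(tr2$V, tr2$times)$intervals[[1]]
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s1$onset, s2$onset, tolerance = 4)
  expect_error(segment_updown(rep(-70, 5), seq_len(5)),
               "smoothing window")
})

test_that("periodic cycles normalize to exactly 1", {
  win <- cbind(seq(0, 4600, by = 1000), seq(400, 5000, by = 1000))
  tr <- make_square_trace(win, T = 5600, dt = 1)
  seg <- segment_updown(tr$V, tr$times)
  cs <- cycle_statistics(seg)
  expect_equal(cs$mean_up, 400, tolerance = 0.05)
  expect_equal(unique(round(cs$normalized, 10)), 1)
  expect_equal(mean(cs$normalized), 1, tolerance = 1e-12)
})

test_that("population UP onsets count synchronized episodes", {
  win <- cbind(c(500, 2500, 4500), c(1500, 3500, 5500))
  tr <- make_square_trace(win, T = 6000, dt = 1)
  V <- cbind(tr$V, tr$V, tr$V, rep(-70, length(tr$V)))
  seg <- segment_updown(V, tr$times)
  pop <- population_up(seg)
  expect_equal(nrow(pop$intervals), 3)
  expect_equal(pop$onset_rate_hz, 3 / 6, tolerance = 1e-6)
})

test_that("Fano factor: ~1 for Poisson counts, 0 for clockwork counts", {
  win <- cbind(seq(0, 39) * 1000, seq(0, 39) * 1000 + 600)
  fx <- make_fixture_raster(30, up_windows = win, rate_up = 25,
                            rate_down = 0, T = 40000, seed = 3)
  tr <- make_square_trace(win, T = 40000, dt = 1)
  seg <- segment_updown(matrix(rep(tr$V, 30), ncol = 30), tr$times)
  ff <- fano_factor(fx$spikes, seg)
  expect_equal(ff$mean, 1, tolerance = 0.25)
  # clockwork: one spike per episode, every episode
  reg <- data.frame(neuron_id = rep(1L, 40), t_ms = win[, 1] + 100)
  seg1 <- segment_updown(tr$V, tr$times)
  ff0 <- fano_factor(reg, seg1)
  expect_equal(unname(ff0$per_neuron[1]), 0)
  # too few episodes -> NA
  few <- segment_updown(make_square_trace(win[1:3, ], T = 4000,
                                          dt = 1)$V,
                        seq_len(4000))
  expect_true(is.na(fano_factor(reg, few)$mean))
})
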