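# firing-rate matrix, NMF with AICc order selection, assembly statistics

test_that("rate matrix converts counts to Hz with the stated window layout", {
  sp <- data.frame(neuron_id = c(1L, 3L), t_ms = c(150, 2100))
  D <- build_rate_matrix(sp, n_neurons = 3, t_range = c(0, 2000),
                         window = 200, step = 50)
  expect_equal(ncol(D), floor((2000 - 200) / 50) + 1)
  # one spike in a 200 ms window -> 5 Hz
  expect_equal(D[1, 1], 5)
  expect_true(all(D[2, ] == 0))          # silent neuron: all-zero row
  expect_true(all(D[3, ] == 0))          # spike outside the range ignored
  # non-overlapping variant: 5 windows per second
  Dn <- build_rate_matrix(sp, 3, c(0, 2000), window = 200, step = 200)
  expect_equal(ncol(Dn), 10)
  expect_error(build_rate_matrix(sp, 3, c(0, 100), window = 200), "window")
})

test_that("NMF objective is non-increasing and rank-1 data is exact", {
  set.seed(2)
  D <- outer(runif(30, 0, 2), runif(50, 0, 2))
  f <- nmf_fit(D, 1)
  expect_true(all(diff(f$objective) <= 1e-10))
  expect_lt(f$rss, 1e-8 * sum(D^2))
  f3 <- nmf_fit(D + matrix(runif(1500, 0, 0.05), 30), 3, init = "random",
                seed = 4)
  expect_true(all(diff(f3$objective) <= 1e-10))
  expect_true(all(f3$B >= 0) && all(f3$C >= 0))
})

test_that("AICc selects the planted rank and capacity nests", {
  set.seed(8)
  B0 <- matrix(0, 40, 2)
  B0[1:18, 1] <- runif(18, 1, 2)
  B0[19:40, 2] <- runif(22, 1, 2)
  C0 <- matrix(rexp(2 * 80), 2, 80)
  D <- B0 %*% C0 + matrix(abs(rnorm(40 * 80, 0, 0.05)), 40, 80)
  res <- select_nmf_order(D, k_range = 1:5, restarts = 2, seed = 3,
                          criterion = "gaussian")
  expect_equal(res$k, 2)
  tr <- res$aicc_trace
  sel <- which(tr$k == res$k)
  expect_lte(tr$rss[sel], tr$rss[sel - 1] * (1 + 1e-8))  # capacity nesting
  # rank-1 outer product selects k = 1
  D1 <- outer(runif(40, 1, 2), runif(80, 0, 3))
  expect_equal(select_nmf_order(D1, k_range = 1:4, restarts = 1,
                                seed = 5)$k, 1)
})

test_that("orders with too many parameters are excluded with a warning", {
  D <- matrix(runif(30), 5, 6)
  expect_warning(res <- select_nmf_order(D, k_range = c(1, 3), restarts = 1),
                 "excluded")
  expect_true(res$k < 3)
})

test_that("planted assemblies are recovered from fixture rasters", {
  for (g in c(2, 3)) {
    members <- split(1:60, rep(1:g, length.out = 60))
    win <- cbind(seq(0, 11) * 1000, seq(0, 11) * 1000 + 500)
    fx <- make_fixture_raster(60, members, win, rate_up = 2, rate_down = 0,
                              rate_assembly = 50, T = 12000, seed = g)
    D <- build_rate_matrix(fx$spikes, 60, c(0, 12000), window = 200,
                           step = 200)
    res <- select_nmf_order(D, k_range = 1:8, restarts = 2, seed = 7 + g)
    expect_equal(res$k, g, info = paste("g =", g))
    sims <- match_assemblies(res$B, fx$membership)
    expect_true(all(sims > 0.8), info = paste("g =", g))
  }
})

test_that("assembly order correlates perfectly in a constructed monotone case", {
  st <- assembly_statistics(orders = c(8, 6, 4, 2),
                            mean_up_ms = c(100, 300, 900, 2700),
                            total_up_ms = c(1000, 3000, 9000, 27000))
  expect_equal(st$cor, -1)
  expect_lt(st$cor_normalized, 0)
  # degenerate input yields the undefined marker
  st0 <- assembly_statistics(c(3, 3, 3), c(100, 200, 300))
  expect_true(is.na(st0$cor))
})

test_that("pattern activation correlation behaves on constructed cases", {
  act <- rbind(sin(1:100) + 1.5, sin(1:100) + 1.5)
  expect_equal(pattern_activation_correlation(list(Cmat = act)), 1)
  anti <- rbind(c(rep(1, 50), rep(0, 50)), c(rep(0, 50), rep(1, 50)))
  expect_lt(pattern_activation_correlation(list(Cmat = anti)), 0)
  expect_true(is.na(pattern_activation_correlation(list(Cmat = act[1, ,
                                                                   drop = FALSE]))))
})
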