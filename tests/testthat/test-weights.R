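# weight ensembles: derived parameters, sampling moments, densities

test_that("derived ensemble parameters satisfy their closed forms", {
  ln <- weight_ensemble("lognormal", sigma2 = 1)
  expect_equal(ln$mu_LN, -0.5 * log(2))
  expect_equal(ln$sigma_LN^2, log(2))
  sg <- weight_ensemble("sparse_gaussian", sigma2 = 1)
  expect_equal(sg$a, pi / 4)
  # analytic moment identities of the half-normal mixture
  expect_equal(sg$a * sg$sigma_SG * sqrt(2 / pi), 1)
  expect_equal(sg$a * sg$sigma_SG^2 - 1, 1)
  sln <- weight_ensemble("sparse_lognormal", sigma2 = 4)
  expect_equal(sln$sigma_SLN^2, log(pi / 2))
  # moment-matched location gives exact mean 1 and variance sigma2
  expect_equal(sln$a * exp(sln$mu_SLN + sln$sigma_SLN^2 / 2), 1)
  expect_equal(sln$a * exp(2 * sln$mu_SLN + 2 * sln$sigma_SLN^2) - 1, 4)
  # the non-moment-matched variant has mean sqrt(a), not 1
  slnp <- weight_ensemble("sparse_lognormal", sigma2 = 4, printed_mu = TRUE)
  expect_equal(slnp$a * exp(slnp$mu_SLN + slnp$sigma_SLN^2 / 2),
               sqrt(slnp$a))
})

test_that("sparse families reject variances below pi/2 - 1", {
  expect_error(weight_ensemble("sparse_gaussian", 0.1), "a <= 1")
  expect_error(weight_ensemble("sparse_lognormal", 0.5), "a <= 1")
  expect_silent(weight_ensemble("sparse_gaussian", pi / 2 - 1 + 1e-9))
  expect_silent(weight_ensemble("lognormal", 0.1))
})

test_that("sampled blocks hit mean 1 and the target variance", {
  n <- 2e5
  for (fam in c("lognormal", "sparse_gaussian", "sparse_lognormal")) {
    for (s2 in c(1, 25, 100)) {
      ens <- weight_ensemble(fam, s2)
      blk <- sample_weights(ens, c(n, 1), seed = 101)
      expect_true(all(blk >= 0))
      rep <- validate_moments(blk, ens, tol_mean = 5, tol_var = 6)
      expect_true(rep$pass,
                  info = sprintf("%s sigma2=%g: mean %.3f var %.1f", fam, s2,
                                 rep$mean, rep$variance))
    }
  }
})

test_that("sparse-Gaussian zero fraction matches 1 - a", {
  ens <- weight_ensemble("sparse_gaussian", 1)
  blk <- sample_weights(ens, c(1000, 100), seed = 7)
  expect_equal(mean(blk == 0), 1 - pi / 4, tolerance = 0.01)
  expect_true(all(blk[blk != 0] > 0))
})

test_that("moment errors shrink roughly as 1/sqrt(n)", {
  ens <- weight_ensemble("lognormal", 4)
  err <- vapply(c(1e3, 1e5), function(n) {
    abs(mean(sample_weights(ens, c(n, 1), seed = 5)) - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("a constant block fails the variance check", {
  ens <- weight_ensemble("lognormal", 1)
  rep <- validate_moments(matrix(1, 100, 100), ens)
  expect_false(rep$ok_var)
  expect_true(rep$ok_mean)
  expect_error(validate_moments(numeric(0), ens), "empty")
})

test_that("nonzero samples follow the printed densities (KS)", {
  set.seed(42)
  n <- 2e4
  ln <- weight_ensemble("lognormal", 1)
  ks1 <- stats::ks.test(sample_weights(ln, c(n, 1)),
                        stats::plnorm, ln$mu_LN, ln$sigma_LN)
  expect_gt(ks1$p.value, 0.01)
  sg <- weight_ensemble("sparse_gaussian", 1)
  x <- sample_weights(sg, c(n, 1))
  x <- x[x > 0]
  half_normal_cdf <- function(q) 2 * stats::pnorm(q, 0, sg$sigma_SG) - 1
  ks2 <- stats::ks.test(x, half_normal_cdf)
  expect_gt(ks2$p.value, 0.01)
})

test_that("block sampling is reproducible and block-structured", {
  W1 <- sample_weight_matrix(40, 10, "sparse_lognormal", sigma_E2 = 4,
                             seed = 9)
  W2 <- sample_weight_matrix(40, 10, "sparse_lognormal", sigma_E2 = 4,
                             seed = 9)
  expect_identical(W1$EE, W2$EE)
  expect_identical(W1$input, W2$input)
  expect_equal(dim(W1$EE), c(40, 40))
  expect_equal(dim(W1$EI), c(40, 10))
  expect_equal(dim(W1$IE), c(10, 40))
  expect_equal(dim(W1$II), c(10, 10))
  # E-sourced blocks carry sigma_E2, I-sourced blocks unit variance
  expect_equal(W1$ensemble_E$sigma2, 4)
  expect_equal(W1$ensemble_I$sigma2, 1)
})
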