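# Connection-weight ensembles: log-normal, sparse-Gaussian and
# sparse-log-normal, all parameterized by (mean = 1, variance sigma2).

#' Define a weight ensemble
#'
#' All three families have mean 1 and variance `sigma2`; the family-specific
#' parameters follow in closed form.
#' \itemize{
#'   \item log-normal: \eqn{\sigma_{LN}^2 = \ln(\sigma^2+1)},
#'     \eqn{\mu_{LN} = -\frac12\ln(\sigma^2+1)}.
#'   \item sparse-Gaussian: a point mass \eqn{(1-a)} at zero plus a
#'     half-normal of width \eqn{\sigma_{SG} = \sqrt{2/\pi}(\sigma^2+1)} with
#'     sparseness \eqn{a = (\pi/2)/(\sigma^2+1)}; requires \eqn{a \le 1},
#'     i.e. \eqn{\sigma^2 \ge \pi/2 - 1}.
#'   \item sparse-log-normal: same \eqn{a}; log-normal component with
#'     \eqn{\sigma_{SLN}^2 = \ln[a(\sigma^2+1)]} and, by moment matching,
#'     \eqn{\mu_{SLN} = \ln(1/a) - \frac12\ln[a(\sigma^2+1)]}. Setting
#'     `printed_mu = TRUE` uses the variant
#'     \eqn{\mu_{SLN} = \ln(1/a) - \frac12\ln(\sigma^2+1)} instead, whose
#'     mean is \eqn{\sqrt a}, not 1.
#' }
#'
#' @param family one of `"lognormal"`, `"sparse_gaussian"`,
#'   `"sparse_lognormal"`.
#' @param sigma2 target variance (> 0).
#' @param printed_mu sparse-log-normal only: use the non-moment-matched
#'   location parameter (see Details).
#' @return object of class `weight_ensemble` with the derived parameters.
#' @export
weight_ensemble <- function(family = c("lognormal", "sparse_gaussian",
                                       "sparse_lognormal"),
                            sigma2 = 1, printed_mu = FALSE) {
  family <- match.arg(family)
  stopifnot(sigma2 > 0)
  derived <- switch(family,
    lognormal = list(mu_LN = -0.5 * log(sigma2 + 1),
                     sigma_LN = sqrt(log(sigma2 + 1))),
    sparse_gaussian = {
      a <- (pi / 2) / (sigma2 + 1)
      if (a > 1) {
        stop("sparse families need sparseness a <= 1, i.e. sigma2 >= pi/2 - 1",
             " (got sigma2 = ", sigma2, ")")
      }
      list(a = a, sigma_SG = sqrt(2 / pi) * (sigma2 + 1))
    },
    sparse_lognormal = {
      a <- (pi / 2) / (sigma2 + 1)
      if (a > 1) {
        stop("sparse families need sparseness a <= 1, i.e. sigma2 >= pi/2 - 1",
             " (got sigma2 = ", sigma2, ")")
      }
      s2 <- log(a * (sigma2 + 1))  # = log(pi/2), always >= 0
      mu <- if (printed_mu) log(1 / a) - 0.5 * log(sigma2 + 1)
            else log(1 / a) - 0.5 * s2
      list(a = a, mu_SLN = mu, sigma_SLN = sqrt(s2))
    })
  out <- c(list(family = family, sigma2 = sigma2, printed_mu = printed_mu),
           derived)
  class(out) <- "weight_ensemble"
  out
}

#' @export
print.weight_ensemble <- function(x, ...) {
  cat(sprintf("weight ensemble: %s, mean 1, variance %g\n", x$family,
              x$sigma2))
  d <- x[setdiff(names(x), c("family", "sigma2", "printed_mu"))]
  cat("  ", paste(sprintf("%s = %.4g", names(d), unlist(d)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Sample a block of connection weights
#'
#' I.i.d. non-negative draws from the ensemble; reproducible under `seed`.
#'
#' @param ensemble a [weight_ensemble()].
#' @param shape integer length 2: (rows, cols); rows index postsynaptic,
#'   cols presynaptic neurons.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return numeric matrix of non-negative weights.
#' @export
sample_weights <- function(ensemble, shape, seed = NULL) {
  stopifnot(inherits(ensemble, "weight_ensemble"), length(shape) == 2)
  n <- as.integer(shape[1]) * as.integer(shape[2])
  if (!is.null(seed)) set.seed(seed)
  x <- switch(ensemble$family,
    lognormal = rlnorm(n, ensemble$mu_LN, ensemble$sigma_LN),
    sparse_gaussian = {
      nz <- runif(n) < ensemble$a
      v <- numeric(n)
      v[nz] <- abs(rnorm(sum(nz), 0, ensemble$sigma_SG))
      v
    },
    sparse_lognormal = {
      nz <- runif(n) < ensemble$a
      v <- numeric(n)
      v[nz] <- rlnorm(sum(nz), ensemble$mu_SLN, ensemble$sigma_SLN)
      v
    })
  matrix(x, nrow = shape[1], ncol = shape[2])
}

#' Check empirical moments of a weight block
#'
#' Compares the empirical mean (target 1), variance (target `sigma2`) and
#' zero fraction (target `1 - a` for the sparse families) of a sampled block
#' with the ensemble targets, using standard-error bands.
#'
#' @param block numeric matrix or vector of sampled weights.
#' @param target the [weight_ensemble()] the block was drawn from.
#' @param tol_mean,tol_var tolerance in units of the respective standard
#'   error (mean: \eqn{sd/\sqrt n}; variance: \eqn{\sqrt{(m_4 - s^4)/n}}).
#' @return list with the empirical moments, their standard errors and
#'   logical `pass`.
#' @export
validate_moments <- function(block, target, tol_mean = 5, tol_var = 5) {
  x <- as.numeric(block)
  n <- length(x)
  if (n == 0) stop("empty weight block")
  m <- mean(x)
  v <- var(x)
  se_mean <- sd(x) / sqrt(n)
  m4 <- mean((x - m)^4)
  se_var <- sqrt(max(m4 - v^2, 0) / n)
  zero_frac <- mean(x == 0)
  ok_mean <- abs(m - 1) <= tol_mean * se_mean
  ok_var <- abs(v - target$sigma2) <= tol_var * se_var
  list(mean = m, variance = v, zero_fraction = zero_frac,
       se_mean = se_mean, se_var = se_var,
       ok_mean = ok_mean, ok_var = ok_var, pass = ok_mean && ok_var)
}

#' Sample the four recurrent weight blocks
#'
#' E-sourced blocks (`EE`, `IE`) use variance `sigma_E2`; I-sourced blocks
#' (`EI`, `II`) have fixed unit variance. All blocks share the ensemble
#' family. Block-specific child seeds are derived from `seed`.
#'
#' @param N_E,N_I population sizes.
#' @param family ensemble family, see [weight_ensemble()].
#' @param sigma_E2 variance of E-to-E and E-to-I weights.
#' @param seed integer master seed.
#' @return list with matrices `EE` (N_E x N_E), `EI` (N_E x N_I), `IE`
#'   (N_I x N_E), `II` (N_I x N_I), `input` (length-N_E afferent weights,
#'   unit variance), plus the ensembles used.
#' @export
sample_weight_matrix <- function(N_E, N_I, family = "lognormal",
                                 sigma_E2 = 1, seed = 1) {
  ens_E <- weight_ensemble(family, sigma_E2)
  ens_I <- weight_ensemble(family, 1.0)
  seeds <- derive_seeds(seed, 5)
  list(EE = sample_weights(ens_E, c(N_E, N_E), seeds[1]),
       EI = sample_weights(ens_I, c(N_E, N_I), seeds[2]),
       IE = sample_weights(ens_E, c(N_I, N_E), seeds[3]),
       II = sample_weights(ens_I, c(N_I, N_I), seeds[4]),
       input = as.numeric(sample_weights(ens_I, c(N_E, 1), seeds[5])),
       ensemble_E = ens_E, ensemble_I = ens_I)
}
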