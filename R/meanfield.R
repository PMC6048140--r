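# Mean-field fixed-point analysis of UP-state existence and stability.
#
# In a homogeneous network firing at a common stationary rate f, every
# receptor gate averages to tau_dn f / (1 + tau_dn f), the recurrent current
# follows by summing receptor conductances at the assumed mean UP-state
# voltage, and the adaptation current averages to a_u(V - V_L) + b_u tau_u f.
# UP states correspond to non-trivial solutions of f = F'(f) =
# F[I_syn(f) - u(f)], with F the fitted single-neuron response function.

#' Mean-field configuration
#'
#' @param fi an `fi_fit` response function (from [fit_response_function()]
#'   or [fi_fit()]).
#' @param gamma_E,gamma_I weight scaling factors.
#' @param N_E,N_I population sizes (`N_I` defaults to `N_E/4`).
#' @param V_mean assumed mean membrane potential during UP states (mV).
#' @param neuron `neuron_params` supplying `a_u`, `b_u`, `tau_u`, `V_L`.
#' @param receptors receptor table.
#' @param mean_J mean connection weight (1 for all ensembles here).
#' @return object of class `meanfield_config`.
#' @export
meanfield_config <- function(fi, gamma_E = 0.1, gamma_I = 0.1,
                             N_E = 1000, N_I = round(N_E / 4),
                             V_mean = -55, neuron = neuron_params(),
                             receptors = receptor_table(), mean_J = 1) {
  stopifnot(inherits(fi, "fi_fit"))
  if (V_mean <= min(receptors$V_R) || V_mean >= neuron$V_peak) {
    stop("V_mean must lie between the lowest reversal potential and V_peak")
  }
  out <- list(fi = fi, gamma_E = gamma_E, gamma_I = gamma_I,
              N_E = N_E, N_I = N_I, V_mean = V_mean, neuron = neuron,
              receptors = receptors, mean_J = mean_J)
  class(out) <- "meanfield_config"
  out
}

#' Mean recurrent synaptic current at a common firing rate
#'
#' @param f common stationary firing rate (Hz), >= 0.
#' @param cfg a `meanfield_config`.
#' @return mean synaptic current (pA); vectorized over `f`.
#' @export
drive_at_rate <- function(f, cfg) {
  tab <- cfg$receptors
  exc <- tab$carrier == "excitatory"
  out <- numeric(length(f))
  for (r in seq_len(nrow(tab))) {
    ms <- mean_gating(f, tab[r, ])
    gam <- if (exc[r]) cfg$gamma_E else cfg$gamma_I
    Npre <- if (exc[r]) cfg$N_E else cfg$N_I
    out <- out + gam * Npre * cfg$mean_J * tab$g[r] *
      (tab$V_R[r] - cfg$V_mean) * ms
  }
  out
}

#' Mean adaptation current at a postsynaptic firing rate
#'
#' \eqn{\langle u \rangle = a_u(V_{mean} - V_L) + b_u \tau_u f}
#' (with \eqn{\tau_u} in seconds for `f` in Hz).
#'
#' @param f postsynaptic firing rate (Hz).
#' @param cfg a `meanfield_config`.
#' @return mean adaptation current (pA); vectorized over `f`.
#' @export
adaptation_at_rate <- function(f, cfg) {
  p <- cfg$neuron
  p$a_u * (cfg$V_mean - p$V_L) + p$b_u * (p$tau_u / 1000) * f
}

#' The self-consistency map F'(f)
#'
#' @param f firing rate(s) (Hz).
#' @param cfg a `meanfield_config`.
#' @return mapped rate(s) \eqn{F[I_{syn}(f) - u(f)]} (Hz).
#' @export
meanfield_map <- function(f, cfg) {
  I <- drive_at_rate(f, cfg) - adaptation_at_rate(f, cfg)
  predict(cfg$fi, current = I + cfg$fi$theta_f)
}

#' Locate the fixed points of the mean-field map
#'
#' Finds all crossings of \eqn{f = F'(f)} by sign-change bracketing on a
#' dense grid followed by bisection, and classifies each crossing by the
#' stability of the fixed-point iteration \eqn{f \leftarrow F'(f)}: stable
#' iff \eqn{|dF'/df| < 1} at the crossing. The regime is `no_up` when only
#' the trivial solution exists, `transient_up` when non-trivial crossings
#' exist but none is stable, and `self_sustained_up` when a stable
#' non-trivial crossing exists.
#'
#' @param cfg a `meanfield_config`.
#' @param f_max upper end of the searched rate range (Hz).
#' @param n_grid grid resolution.
#' @return object of class `fixed_point_report` with `fixed_points`
#'   (data.frame: `f`, `slope`, `stable`), `regime`, and the map samples.
#' @export
solve_fixed_points <- function(cfg, f_max = 700, n_grid = 1401) {
  grid <- seq(0, f_max, length.out = n_grid)
  Fp <- meanfield_map(grid, cfg)
  if (any(!is.finite(Fp))) stop("mean-field map non-finite on the grid")
  g <- Fp - grid
  fp <- numeric(0)
  sign_change <- which(g[-1] * g[-length(g)] < 0)
  for (i in sign_change) {
    root <- uniroot(function(f) meanfield_map(f, cfg) - f,
                    lower = grid[i], upper = grid[i + 1],
                    tol = 1e-8)$root
    fp <- c(fp, root)
  }
  # exact zeros on the grid (besides the guaranteed trivial one at f = 0)
  fp <- c(fp, grid[-1][g[-1] == 0])
  fp <- sort(unique(fp))
  h <- max(f_max * 1e-5, 1e-4)
  slope <- vapply(fp, function(f0) {
    (meanfield_map(f0 + h, cfg) - meanfield_map(max(f0 - h, 0), cfg)) /
      (f0 + h - max(f0 - h, 0))
  }, numeric(1))
  stable <- abs(slope) < 1
  nontrivial <- fp > 1e-6
  regime <- if (!any(nontrivial)) "no_up"
            else if (any(stable & nontrivial)) "self_sustained_up"
            else "transient_up"
  out <- list(fixed_points = data.frame(f = fp, slope = slope,
                                        stable = stable),
              regime = regime, grid = grid, map = Fp, cfg = cfg)
  class(out) <- "fixed_point_report"
  out
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat(sprintf("mean-field fixed points (gamma_E = %g, gamma_I = %g, N_E = %d):\n",
              x$cfg$gamma_E, x$cfg$gamma_I, x$cfg$N_E))
  fp <- x$fixed_points
  if (nrow(fp) == 0) {
    cat("  none found on the grid\n")
  } else {
    for (i in seq_len(nrow(fp))) {
      cat(sprintf("  f* = %8.3f Hz, map slope %+.3f (%s)\n", fp$f[i],
                  fp$slope[i], if (fp$stable[i]) "stable" else "unstable"))
    }
  }
  cat("  regime:", x$regime, "\n")
  invisible(x)
}

#' @export
plot.fixed_point_report <- function(x, ...) {
  plot(x$grid, x$map, type = "l", col = "blue", xlab = "f (Hz)",
       ylab = "F'(f) (Hz)", ...)
  graphics::abline(0, 1, col = "red")
  graphics::points(x$fixed_points$f, x$fixed_points$f,
                   pch = ifelse(x$fixed_points$stable, 19, 1))
  invisible(x)
}

#' Critical excitatory scaling factor for a target regime
#'
#' Bisects `gamma_E` (optionally with `gamma_I` tied to it) to the boundary
#' where `regime_target` first appears.
#'
#' @param gamma_I inhibitory scaling factor, or `NULL` to keep
#'   `gamma_I = gamma_E` along the search.
#' @param cfg a `meanfield_config` (its `gamma_E`/`gamma_I` are overridden
#'   during the search).
#' @param regime_target `"self_sustained_up"` (default) or `"transient_up"`
#'   (boundary where any non-trivial crossing appears).
#' @param bracket search bracket for `gamma_E`.
#' @param tol bisection tolerance.
#' @return critical `gamma_E`.
#' @export
critical_gamma_E <- function(gamma_I = NULL, cfg,
                             regime_target = c("self_sustained_up",
                                               "transient_up"),
                             bracket = c(0.005, 0.5), tol = 1e-4) {
  regime_target <- match.arg(regime_target)
  in_regime <- function(gE) {
    cfg$gamma_E <- gE
    cfg$gamma_I <- if (is.null(gamma_I)) gE else gamma_I
    rep <- solve_fixed_points(cfg)
    if (regime_target == "self_sustained_up") {
      rep$regime == "self_sustained_up"
    } else {
      rep$regime != "no_up"
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (in_regime(lo)) stop("lower bracket already in target regime")
  if (!in_regime(hi)) stop("target regime not reached at upper bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (in_regime(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
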