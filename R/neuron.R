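# Single AdEx neuron: parameters, one-step integrator, f-I measurement,
# rheobase and the quartic response-function fit used by the mean-field
# analysis.

#' AdEx neuron parameters
#'
#' Returns the parameter set of the adaptive exponential integrate-and-fire
#' neuron with spike-frequency adaptation (SFA). Defaults are the reference
#' values used throughout the package.
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param V_L leak reversal potential (mV).
#' @param Delta_T spike slope factor (mV).
#' @param V_T effective spike threshold (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param V_peak spike-detection ceiling (mV); reaching it counts as a spike.
#' @param tau_u adaptation time constant (ms).
#' @param a_u subthreshold adaptation conductance (nS).
#' @param b_u spike-triggered adaptation increment (pA).
#' @param t_ref refractory shaping constant (ms); the exponential
#'   spike-generation term is suppressed by
#'   \eqn{1 - \exp[-((t - t^{sp})_+ / t_{ref})^{20}]}.
#' @return object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params()           # SFA on
#' p0 <- neuron_params(a_u = 0, b_u = 0)  # SFA off
#' @export
neuron_params <- function(C = 150, g_L = 10.005, V_L = -70, Delta_T = 2,
                          V_T = -55, V_reset = -55, V_peak = 20,
                          tau_u = 200, a_u = 4.0, b_u = 50.0, t_ref = 2) {
  stopifnot(C > 0, Delta_T > 0, tau_u > 0, t_ref > 0)
  p <- list(C = C, g_L = g_L, V_L = V_L, Delta_T = Delta_T, V_T = V_T,
            V_reset = V_reset, V_peak = V_peak, tau_u = tau_u,
            a_u = a_u, b_u = b_u, t_ref = t_ref)
  class(p) <- "neuron_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("AdEx neuron parameters:\n")
  cat(sprintf("  C = %g pF, g_L = %g nS, V_L = %g mV, Delta_T = %g mV\n",
              x$C, x$g_L, x$V_L, x$Delta_T))
  cat(sprintf("  V_T = %g mV, V_reset = %g mV, V_peak = %g mV\n",
              x$V_T, x$V_reset, x$V_peak))
  cat(sprintf("  SFA: tau_u = %g ms, a_u = %g nS, b_u = %g pA; t_ref = %g ms\n",
              x$tau_u, x$a_u, x$b_u, x$t_ref))
  invisible(x)
}

#' Initial neuron state
#'
#' @param V membrane potential (mV); defaults to the leak reversal.
#' @param u adaptation current (pA).
#' @param t_last_spike time of the most recent spike (ms); `-Inf` means the
#'   neuron has never spiked so the refractory factor is 1.
#' @param params `neuron_params` supplying the default `V`.
#' @return object of class `neuron_state`.
#' @export
neuron_state <- function(V = NULL, u = 0, t_last_spike = -Inf,
                         params = neuron_params()) {
  if (is.null(V)) V <- params$V_L
  s <- list(V = V, u = u, t_last_spike = t_last_spike)
  class(s) <- "neuron_state"
  s
}

# refractory suppression of the exponential term; safe for large exponents
refractory_factor <- function(dt_since_spike, t_ref = 2) {
  if (!is.finite(dt_since_spike)) return(1)
  r <- max(dt_since_spike, 0) / t_ref
  if (r > 3) return(1)
  1 - exp(-r^20)
}

# membrane/adaptation derivatives; exponential argument capped to avoid
# overflow when the trajectory diverges during spike generation
adex_deriv <- function(V, u, I_total, t, t_sp, p) {
  expo <- exp(pmin((V - p$V_T) / p$Delta_T, 30))
  R <- refractory_factor(t - t_sp, p$t_ref)
  dV <- (-p$g_L * (V - p$V_L) + p$g_L * p$Delta_T * expo * R -
           u + I_total) / p$C
  # adaptation sees V clipped at V_peak; beyond it the trajectory is the
  # spike-generation divergence, not a physical potential
  du <- (-u + p$a_u * (min(V, p$V_peak) - p$V_L)) / p$tau_u
  c(dV, du)
}

#' Advance a single neuron by one time step
#'
#' One second-order Runge-Kutta (Heun) step of the AdEx membrane and
#' adaptation equations under a constant total current. If the membrane
#' crosses `V_peak` within the step, a spike is flagged, its time is obtained
#' by linear interpolation of the trajectory, the membrane is reset and the
#' adaptation current incremented by `b_u`. After each spike the
#' spike-generation term is smoothly suppressed for about `t_ref`
#' (refractory factor) and spike detection is disabled within `t_ref` of the
#' last spike, so inter-spike intervals are never shorter than `t_ref`.
#'
#' @param state a `neuron_state`.
#' @param params a `neuron_params`.
#' @param I_total total input current over the step (pA).
#' @param t current time (ms).
#' @param dt time step (ms), > 0.
#' @return list with the updated `state` and logical `spike`.
#' @export
step_neuron <- function(state, params, I_total, t, dt) {
  stopifnot(dt > 0, is.finite(I_total))
  p <- params
  V <- state$V; u <- state$u; tsp <- state$t_last_spike
  d1 <- adex_deriv(V, u, I_total, t, tsp, p)
  V1 <- V + dt * d1[1]; u1 <- u + dt * d1[2]
  d2 <- adex_deriv(V1, u1, I_total, t + dt, tsp, p)
  V_new <- V + dt / 2 * (d1[1] + d2[1])
  u_new <- u + dt / 2 * (d1[2] + d2[2])
  if (!is.finite(u_new) || is.nan(V_new)) {
    stop("integration failure: non-finite state after step (dt too large?)")
  }
  spike <- FALSE
  if (V_new >= p$V_peak) {
    if ((t - tsp) >= p$t_ref) {
      spike <- TRUE
      t_star <- t + dt * min(1, max(0, (p$V_peak - V) / (V_new - V)))
      state$t_last_spike <- t_star
      V_new <- p$V_reset
      u_new <- u_new + p$b_u
    } else {
      V_new <- p$V_peak
    }
  }
  state$V <- V_new
  state$u <- u_new
  list(state = state, spike = spike)
}

#' Measure the steady-state f-I curve
#'
#' Simulates the neuron at each constant current, discards an initial window
#' and returns the steady firing rate (spike count / remaining time). With
#' SFA disabled (`a_u = b_u = 0` in `params`) the curve is the response
#' function used by the mean-field analysis.
#'
#' @param params `neuron_params`.
#' @param currents numeric vector of input currents (pA).
#' @param sim_time simulated time per current (ms).
#' @param discard initial transient discarded from the rate estimate (ms).
#' @param dt integration step (ms).
#' @return data.frame with columns `current` (pA) and `rate` (Hz).
#' @export
measure_fi_curve <- function(params = neuron_params(a_u = 0, b_u = 0),
                             currents, sim_time = 3000, discard = 1000,
                             dt = 0.05) {
  stopifnot(sim_time > 0, discard >= 0, sim_time > discard)
  rates <- vapply(currents, function(I) {
    st <- simulate_neuron_cpp(unclass(params), I, sim_time, dt)
    n <- sum(st >= discard)
    1000 * n / (sim_time - discard)  # ms -> s
  }, numeric(1))
  data.frame(current = currents, rate = rates)
}

#' Rheobase by bisection
#'
#' Finds the minimal constant current producing sustained repetitive firing,
#' by bisection on the steady firing rate between a silent and a firing
#' bracket.
#'
#' @param params `neuron_params`; use `a_u = 0, b_u = 0` for the
#'   no-adaptation rheobase.
#' @param bracket numeric length 2, currents (pA) bracketing the threshold.
#' @param tol bisection tolerance on the current (pA).
#' @param sim_time,discard,dt as in [measure_fi_curve()].
#' @return rheobase current (pA).
#' @export
find_rheobase <- function(params = neuron_params(a_u = 0, b_u = 0),
                          bracket = c(50, 400), tol = 0.05,
                          sim_time = 4000, discard = 1000, dt = 0.05) {
  fires <- function(I) {
    st <- simulate_neuron_cpp(unclass(params), I, sim_time, dt)
    sum(st >= discard) >= 2
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo)) stop("lower bracket already fires; lower it")
  if (!fires(hi)) stop("upper bracket silent; raise it")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Fit the quartic response function to an f-I curve
#'
#' Fits \eqn{F(I) = \Theta(I-\theta_f)[A x + B x^2 + C x^3 + D x^4]},
#' \eqn{x = I - \theta_f}, by least squares constrained through the origin.
#' The rheobase \eqn{\theta_f} is taken from the largest silent current on
#' the grid, refined by bisection when `params` is supplied.
#'
#' @param fi_points data.frame with columns `current`, `rate`
#'   (from [measure_fi_curve()]).
#' @param params optional `neuron_params`; when given, \eqn{\theta_f} is
#'   refined by [find_rheobase()] between the bracketing grid points.
#' @param valid_range_max fit window: only points with
#'   \eqn{I - \theta_f <} this value (pA) enter the fit.
#' @return object of class `fi_fit` with elements `theta_f`, `coef`
#'   (A, B, C, D), `valid_range_max`, `rms` (residual RMS over the fitted
#'   grid) and `points`.
#' @export
fit_response_function <- function(fi_points, params = NULL,
                                  valid_range_max = 1840) {
  stopifnot(all(c("current", "rate") %in% names(fi_points)))
  if (all(fi_points$rate == 0)) {
    stop("no rheobase: all sampled rates are zero")
  }
  silent <- fi_points$current[fi_points$rate == 0]
  firing <- fi_points$current[fi_points$rate > 0]
  theta_grid <- if (length(silent)) max(silent) else min(firing)
  theta_f <- theta_grid
  if (!is.null(params)) {
    hi <- min(firing[firing > theta_grid])
    theta_f <- find_rheobase(params, bracket = c(theta_grid, hi), tol = 0.05)
  }
  x <- fi_points$current - theta_f
  keep <- x > 0 & x < valid_range_max
  xx <- x[keep]; yy <- fi_points$rate[keep]
  if (length(xx) < 4) stop("too few suprathreshold points for a quartic fit")
  fit <- lm(yy ~ 0 + xx + I(xx^2) + I(xx^3) + I(xx^4))
  cf <- unname(coef(fit))
  out <- list(theta_f = theta_f,
              coef = c(A = cf[1], B = cf[2], Ccoef = cf[3], D = cf[4]),
              valid_range_max = valid_range_max,
              rms = sqrt(mean(fit$residuals^2)),
              points = fi_points[keep, , drop = FALSE])
  class(out) <- "fi_fit"
  out
}

#' Construct a response function from known coefficients
#'
#' @param theta_f rheobase (pA).
#' @param A,B,Ccoef,D quartic coefficients (Hz/pA .. Hz/pA^4).
#' @param valid_range_max validity bound on \eqn{I - \theta_f} (pA); the
#'   response saturates at its value there for larger currents.
#' @return object of class `fi_fit`.
#' @export
fi_fit <- function(theta_f, A, B, Ccoef, D, valid_range_max = 1840) {
  out <- list(theta_f = theta_f,
              coef = c(A = A, B = B, Ccoef = Ccoef, D = D),
              valid_range_max = valid_range_max, rms = NA_real_,
              points = NULL)
  class(out) <- "fi_fit"
  out
}

#' @export
coef.fi_fit <- function(object, ...) object$coef

#' Evaluate a fitted response function
#'
#' @param object an `fi_fit`.
#' @param current input currents I (pA).
#' @param saturate if TRUE (default) the response is held at its value at the
#'   validity bound for currents beyond it; the fitted quartic is meaningless
#'   out there.
#' @param ... unused.
#' @return firing rates (Hz).
#' @export
predict.fi_fit <- function(object, current, saturate = TRUE, ...) {
  x <- current - object$theta_f
  if (saturate) x <- pmin(x, object$valid_range_max)
  cf <- object$coef
  ifelse(x > 0, cf[1] * x + cf[2] * x^2 + cf[3] * x^3 + cf[4] * x^4, 0)
}

#' @export
print.fi_fit <- function(x, ...) {
  cat("Quartic response-function fit f(I - theta_f):\n")
  cat(sprintf("  theta_f = %.2f pA\n", x$theta_f))
  cat(sprintf("  A = %.4g Hz/pA, B = %.4g, C = %.4g, D = %.4g\n",
              x$coef[1], x$coef[2], x$coef[3], x$coef[4]))
  cat(sprintf("  valid for I - theta_f < %g pA; residual RMS %.3g Hz\n",
              x$valid_range_max, x$rms))
  invisible(x)
}

#' Single-neuron voltage trace under constant current
#'
#' Convenience wrapper around the compiled integrator that also records the
#' membrane trajectory, e.g. to display adaptation under a current step.
#'
#' @inheritParams measure_fi_curve
#' @param I constant input current (pA).
#' @return list with `spike_times` (ms), `time` (ms) and `V` (mV) sampled at
#'   every integration step.
#' @export
simulate_neuron <- function(params = neuron_params(), I = 300,
                            sim_time = 2000, dt = 0.05) {
  res <- simulate_neuron_trace_cpp(unclass(params), I, sim_time, dt)
  list(spike_times = res$spikes, time = res$time, V = res$V)
}
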