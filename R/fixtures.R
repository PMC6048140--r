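# Deterministic fixture generators: UP/DOWN-modulated Poisson rasters with
# planted co-active assemblies, for testing the analysis modules
# independently of the simulator.

#' Generate a fixture raster with planted assemblies
#'
#' Produces square-wave UP/DOWN-modulated Poisson spike trains: during each
#' UP window neurons fire at `rate_up`, between windows at `rate_down`, and
#' the members of the assembly active in that window fire at
#' `rate_assembly`. Assemblies are activated cyclically across UP windows.
#' Ground truth (segmentation and membership) is returned alongside.
#'
#' @param n_neurons number of neurons.
#' @param assemblies list of integer vectors (neuron ids) defining the
#'   planted assemblies; may be empty for plain UP/DOWN modulation.
#' @param up_windows 2-column matrix (onset, offset in ms) of UP windows.
#' @param rate_up baseline rate during UP states (Hz).
#' @param rate_down rate during DOWN states (Hz).
#' @param rate_assembly rate of active-assembly members during their UP
#'   window (Hz).
#' @param T total duration (ms); defaults to the last UP offset.
#' @param seed integer seed.
#' @return list with `spikes` (data.frame `neuron_id`, `t_ms`),
#'   `up_windows`, `membership` (neurons x assemblies 0/1 matrix),
#'   `active_assembly` (per UP window), `T`.
#' @export
make_fixture_raster <- function(n_neurons, assemblies = list(),
                                up_windows, rate_up = 10, rate_down = 0,
                                rate_assembly = 40, T = NULL, seed = 1) {
  up_windows <- matrix(as.numeric(up_windows), ncol = 2)
  stopifnot(all(up_windows[, 2] > up_windows[, 1]))
  if (any(c(rate_up, rate_down, rate_assembly) < 0)) {
    stop("rates must be non-negative")
  }
  bad <- unlist(assemblies)[!unlist(assemblies) %in% seq_len(n_neurons)]
  if (length(bad)) stop("assembly members outside 1..n_neurons")
  if (is.null(T)) T <- if (nrow(up_windows)) max(up_windows[, 2]) else 1000
  set.seed(seed)
  g <- length(assemblies)
  active <- if (g > 0 && nrow(up_windows) > 0) {
    rep_len(seq_len(g), nrow(up_windows))
  } else integer(0)
  poisson_times <- function(rate, t0, t1) {
    if (rate <= 0 || t1 <= t0) return(numeric(0))
    n <- rpois(1, rate * (t1 - t0) / 1000)
    sort(runif(n, t0, t1))
  }
  ids <- integer(0); ts <- numeric(0)
  for (i in seq_len(n_neurons)) {
    # DOWN-state background over the complement of the UP windows
    edges <- c(0, as.numeric(t(up_windows)), T)
    down_t <- unlist(lapply(seq(1, length(edges) - 1, by = 2), function(k) {
      poisson_times(rate_down, edges[k], edges[k + 1])
    }))
    up_t <- unlist(lapply(seq_len(nrow(up_windows)), function(w) {
      r <- rate_up
      if (g > 0 && i %in% assemblies[[active[w]]]) r <- rate_assembly
      poisson_times(r, up_windows[w, 1], up_windows[w, 2])
    }))
    tt <- c(down_t, up_t)
    ids <- c(ids, rep.int(i, length(tt)))
    ts <- c(ts, tt)
  }
  ord <- order(ts, ids)
  membership <- matrix(0, n_neurons, max(g, 1))
  for (a in seq_len(g)) membership[assemblies[[a]], a] <- 1
  list(spikes = data.frame(neuron_id = ids[ord], t_ms = ts[ord]),
       up_windows = up_windows, membership = membership[, seq_len(max(g, 1)),
                                                        drop = FALSE],
       active_assembly = active, T = T)
}

#' Square-wave membrane-trace fixture
#'
#' Alternating DOWN/UP plateau trace for exercising the segmentation.
#'
#' @param up_windows 2-column matrix (onset, offset, ms).
#' @param T total duration (ms).
#' @param dt sample interval (ms).
#' @param V_up,V_down plateau potentials (mV).
#' @return list with `V`, `times`.
#' @export
make_square_trace <- function(up_windows, T, dt = 1, V_up = -55,
                              V_down = -70) {
  times <- seq(dt, T, by = dt)
  V <- rep(V_down, length(times))
  up_windows <- matrix(as.numeric(up_windows), ncol = 2)
  for (k in seq_len(nrow(up_windows))) {
    V[times > up_windows[k, 1] & times <= up_windows[k, 2]] <- V_up
  }
  list(V = V, times = times)
}
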