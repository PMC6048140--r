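# UP/DOWN segmentation of membrane traces, cycle statistics, phase-diagram
# summaries and Fano factors of UP-state spike counts.

#' Detection parameters for UP/DOWN segmentation
#'
#' @param threshold detection threshold (mV); the midpoint between the DOWN
#'   (~ -70 mV) and UP (~ -55 mV) plateaus.
#' @param smooth_window boxcar smoothing window (ms).
#' @param min_duration minimum accepted segment duration (ms), applied to
#'   both UP and DOWN segments.
#' @param merge_gap DOWN gaps up to this length (ms) between UP segments are
#'   merged into one UP state.
#' @return named list of detection parameters.
#' @export
detection_params <- function(threshold = -62, smooth_window = 10,
                             min_duration = 50, merge_gap = 50) {
  list(threshold = threshold, smooth_window = smooth_window,
       min_duration = min_duration, merge_gap = merge_gap)
}

# boxcar smoothing with shrinking windows at the edges
boxcar <- function(v, k) {
  if (k <= 1) return(v)
  cs <- cumsum(c(0, v))
  n <- length(v)
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

segment_one <- function(v, times, par) {
  dt <- times[2] - times[1]
  k <- max(1L, round(par$smooth_window / dt))
  up <- boxcar(v, k) > par$threshold
  r <- rle(up)
  # merge short DOWN gaps between UP segments
  gap_runs <- which(!r$values & r$lengths * dt <= par$merge_gap)
  interior <- gap_runs[gap_runs > 1 & gap_runs < length(r$values)]
  if (length(interior)) {
    r$values[interior] <- TRUE
    up <- inverse.rle(r)
    r <- rle(up)
  }
  # drop UP segments shorter than the minimum duration
  short_up <- which(r$values & r$lengths * dt < par$min_duration)
  if (length(short_up)) {
    r$values[short_up] <- FALSE
    up <- inverse.rle(r)
    r <- rle(up)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  iup <- which(r$values)
  if (!length(iup)) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  # interval convention: [time of first sample, time after last sample)
  data.frame(onset = times[starts[iup]] - dt, offset = times[ends[iup]])
}

#' Segment membrane traces into UP and DOWN states
#'
#' Smooths each trace with a boxcar, thresholds it, merges brief DOWN gaps
#' and discards UP segments shorter than the minimum duration.
#'
#' @param traces numeric matrix (time x neuron) of membrane potentials (mV),
#'   or a `network_sim` (its recorded traces after the transient are used).
#' @param times sample times (ms), regular grid; ignored for a
#'   `network_sim`.
#' @param params detection parameters, see [detection_params()]; for a
#'   `network_sim` the defaults come from its config.
#' @param ids optional neuron ids labelling the trace columns.
#' @return object of class `updown_seg`: per-neuron data.frames of UP
#'   intervals (`onset`, `offset` in ms) plus the analysis window.
#' @export
segment_updown <- function(traces, times = NULL, params = detection_params(),
                           ids = NULL) {
  if (inherits(traces, "network_sim")) {
    sim <- traces
    keep <- sim$trace_times >= sim$config$network$T_transient
    times <- sim$trace_times[keep]
    ids <- sim$trace_ids
    params <- modifyList(detection_params(), sim$config$detection)
    traces <- sim$traces[keep, , drop = FALSE]
  }
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  stopifnot(length(times) == nrow(traces))
  dt <- times[2] - times[1]
  if (nrow(traces) * dt < params$smooth_window) {
    stop("trace shorter than the smoothing window")
  }
  if (is.null(ids)) ids <- seq_len(ncol(traces))
  intervals <- lapply(seq_len(ncol(traces)), function(j) {
    segment_one(traces[, j], times, params)
  })
  names(intervals) <- as.character(ids)
  out <- list(intervals = intervals, ids = ids, params = params,
              window = c(times[1] - dt, times[length(times)]))
  class(out) <- "updown_seg"
  out
}

#' @export
print.updown_seg <- function(x, ...) {
  n_up <- vapply(x$intervals, nrow, 1L)
  cat(sprintf("UP/DOWN segmentation of %d traces over %.1f s\n",
              length(x$intervals), diff(x$window) / 1000))
  cat(sprintf("  UP episodes per neuron: median %g (range %d-%d)\n",
              stats::median(n_up), min(n_up), max(n_up)))
  invisible(x)
}

#' UP-DOWN cycle statistics
#'
#' A cycle is an UP state plus the consecutive DOWN state (onset-to-onset).
#' Cycle durations are pooled over neurons and normalized by the pooled mean
#' cycle duration, so the normalized samples have mean 1 by construction.
#'
#' @param seg an `updown_seg`.
#' @return object of class `cycle_stats` with `mean_up`, `mean_cycle` (ms),
#'   `up_durations`, `cycle_durations`, `normalized` samples and the number
#'   of contributing neurons; with no cycles an empty-stats marker
#'   (`n_cycles = 0`) is returned rather than an error.
#' @export
cycle_statistics <- function(seg) {
  ups <- unlist(lapply(seg$intervals, function(iv) iv$offset - iv$onset))
  cycles <- unlist(lapply(seg$intervals, function(iv) {
    if (nrow(iv) < 2) return(numeric(0))
    diff(iv$onset)
  }))
  out <- list(
    mean_up = if (length(ups)) mean(ups) else NA_real_,
    mean_cycle = if (length(cycles)) mean(cycles) else NA_real_,
    up_durations = ups, cycle_durations = cycles,
    normalized = if (length(cycles)) cycles / mean(cycles) else numeric(0),
    n_cycles = length(cycles),
    n_neurons = length(seg$intervals))
  class(out) <- "cycle_stats"
  out
}

#' @export
print.cycle_stats <- function(x, ...) {
  if (x$n_cycles == 0) {
    cat("cycle statistics: no complete UP-DOWN cycles\n")
  } else {
    cat(sprintf("cycle statistics: %d cycles from %d neurons\n", x$n_cycles,
                x$n_neurons))
    cat(sprintf("  mean UP %.0f ms, mean cycle %.0f ms\n", x$mean_up,
                x$mean_cycle))
  }
  invisible(x)
}

#' Count modes of the normalized cycle-duration distribution
#'
#' Kernel-density peak count of pooled normalized cycle durations; peaks
#' below `prominence` times the global maximum are ignored. Used to contrast
#' multimodal (large weight variance) against unimodal (small variance)
#' cycle distributions.
#'
#' @param stats a `cycle_stats`.
#' @param bw kernel bandwidth (in normalized-duration units).
#' @param prominence minimum relative height of a counted peak.
#' @return integer number of modes (0 when there are no cycles).
#' @export
count_cycle_modes <- function(stats, bw = 0.12, prominence = 0.08) {
  x <- stats$normalized
  if (length(x) < 10) return(0L)
  d <- density(x, bw = bw, from = 0, to = max(3, max(x)))
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[pk] >= prominence * max(y))
}

#' Population UP states
#'
#' Marks the population as UP wherever at least `frac` of the segmented
#' neurons are simultaneously in an UP state, and returns the population
#' intervals plus the UP-onset rate (the slow-oscillation frequency).
#'
#' @param seg an `updown_seg`.
#' @param frac participation threshold (default 0.5).
#' @param dt evaluation grid (ms).
#' @return list with `intervals` (onset/offset data.frame), `onset_rate_hz`
#'   and the analysis duration (s).
#' @export
population_up <- function(seg, frac = 0.5, dt = 1) {
  grid <- seq(seg$window[1], seg$window[2], by = dt)
  n_up <- numeric(length(grid))
  for (iv in seg$intervals) {
    for (k in seq_len(nrow(iv))) {
      n_up <- n_up + (grid >= iv$onset[k] & grid < iv$offset[k])
    }
  }
  up <- n_up >= frac * length(seg$intervals)
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  iup <- which(r$values)
  intervals <- data.frame(onset = grid[starts[iup]], offset = grid[ends[iup]])
  dur_s <- diff(seg$window) / 1000
  list(intervals = intervals, onset_rate_hz = nrow(intervals) / dur_s,
       duration_s = dur_s)
}

#' Fano factor of UP-state spike counts
#'
#' For each segmented neuron, spikes are counted in fixed-length windows
#' aligned at the onsets of UP episodes at least as long as the window, and
#' the Fano factor is the across-episode count variance divided by the mean
#' count. Spiking between UP states is thereby excluded, and the fixed
#' window makes counts comparable across episodes of unequal length and
#' across recordings of different duration (a window tied to the shortest
#' episode shrinks as recordings grow, which makes the statistic depend on
#' run length). Neurons with fewer than `min_episodes` qualifying episodes,
#' or zero mean count, yield `NA`.
#'
#' @param spikes spike data.frame (`neuron_id`, `t_ms`), e.g. from
#'   [analysis_spikes()].
#' @param seg an `updown_seg` whose ids match `neuron_id` entries.
#' @param window count-window length (ms); UP episodes shorter than this
#'   are excluded.
#' @param min_episodes minimum number of qualifying UP episodes per neuron.
#' @return list with `per_neuron` (named vector of Fano factors) and `mean`
#'   (average over neurons with a defined value).
#' @export
fano_factor <- function(spikes, seg, window = 200, min_episodes = 5) {
  per <- vapply(seq_along(seg$intervals), function(j) {
    iv <- seg$intervals[[j]]
    iv <- iv[iv$offset - iv$onset >= window, , drop = FALSE]
    if (nrow(iv) < min_episodes) return(NA_real_)
    st <- spikes$t_ms[spikes$neuron_id == seg$ids[j]]
    counts <- vapply(iv$onset, function(on) {
      sum(st >= on & st < on + window)
    }, numeric(1))
    if (mean(counts) == 0) return(NA_real_)
    var(counts) / mean(counts)
  }, numeric(1))
  names(per) <- as.character(seg$ids)
  list(per_neuron = per,
       mean = if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE))
}

#' Phase-diagram sweep of UP-state statistics
#'
#' Runs one simulation per grid cell (fixed per-cell seeds derived from the
#' base seed), segments the recorded excitatory traces and summarizes mean
#' UP duration, continuity, population onset rate and Fano factor. Cells
#' whose simulation fails are flagged rather than aborting the sweep.
#'
#' @param base a `run_config` used for every cell.
#' @param cells data.frame whose columns override, per cell, any of
#'   `gamma_E`, `gamma_I`, `sigma_E2`.
#' @param trace_n_E number of excitatory membrane traces recorded and
#'   segmented per cell.
#' @return `cells` augmented with `mean_up_ms`, `mean_cycle_ms`,
#'   `continuous_frac` (fraction of the analysis window spent UP),
#'   `near_continuous` flag, `onset_rate_hz`, `fano`, `failed`.
#' @export
updown_phase_diagram <- function(base, cells, trace_n_E = 32) {
  stopifnot(inherits(base, "run_config"), nrow(cells) >= 1)
  seeds <- derive_seeds(base$network$seed, nrow(cells))
  out <- cells
  out$mean_up_ms <- NA_real_
  out$mean_cycle_ms <- NA_real_
  out$continuous_frac <- NA_real_
  out$near_continuous <- NA
  out$onset_rate_hz <- NA_real_
  out$fano <- NA_real_
  out$failed <- FALSE
  for (i in seq_len(nrow(cells))) {
    cfg <- unclass(base)
    for (nm in intersect(names(cells), c("gamma_E", "gamma_I"))) {
      cfg$network[[nm]] <- cells[[nm]][i]
    }
    if ("sigma_E2" %in% names(cells)) {
      cfg$weights$sigma_E2 <- cells$sigma_E2[i]
    }
    cfg$network$seed <- seeds[i]
    cfg$network$trace_n_E <- trace_n_E
    cfg$network$trace_n_I <- 0L
    res <- tryCatch({
      sim <- run_simulation(validate_config(cfg))
      seg <- segment_updown(sim)
      cs <- cycle_statistics(seg)
      pop <- population_up(seg)
      fano <- fano_factor(analysis_spikes(sim, "E"), seg)
      tot_up <- sum(unlist(lapply(seg$intervals,
                                  function(iv) sum(iv$offset - iv$onset))))
      frac <- tot_up / (diff(seg$window) * length(seg$intervals))
      list(mean_up = cs$mean_up, mean_cycle = cs$mean_cycle, frac = frac,
           onset = pop$onset_rate_hz, fano = fano$mean)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$failed[i] <- TRUE
      next
    }
    out$mean_up_ms[i] <- res$mean_up
    out$mean_cycle_ms[i] <- res$mean_cycle
    out$continuous_frac[i] <- res$frac
    out$near_continuous[i] <- is.finite(res$frac) && res$frac > 0.8
    out$onset_rate_hz[i] <- res$onset
    out$fano[i] <- res$fano
  }
  out
}
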