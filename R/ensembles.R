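# Cell-assembly extraction: neuron x time rate matrix, non-negative matrix
# factorization (multiplicative updates) with AICc order selection, and
# assembly activation statistics.

#' Build the neuron x time firing-rate matrix
#'
#' Entry (i, b) is the spike count of excitatory neuron i in window b
#' divided by the window length, in Hz. The default 200 ms window sliding at
#' 50 ms samples the population rate vector at 20 Hz; `step = window` gives
#' non-overlapping windows.
#'
#' @param spikes spike data.frame (`neuron_id`, `t_ms`), excitatory cells.
#' @param n_neurons number of rows (neuron ids 1..n_neurons).
#' @param t_range numeric length 2: analysed interval (ms).
#' @param window window length (ms).
#' @param step window step (ms).
#' @return object of class `rate_matrix`: non-negative matrix with
#'   attributes `window`, `step`, `bin_times` (window start times, ms).
#' @export
build_rate_matrix <- function(spikes, n_neurons, t_range,
                              window = 200, step = 50) {
  T <- diff(t_range)
  if (window > T) stop("window longer than the analysed interval")
  starts <- seq(t_range[1], t_range[2] - window, by = step)
  D <- matrix(0, nrow = n_neurons, ncol = length(starts))
  sp <- spikes[spikes$t_ms >= t_range[1] & spikes$t_ms < t_range[2], ]
  for (b in seq_along(starts)) {
    sel <- sp$t_ms >= starts[b] & sp$t_ms < starts[b] + window
    if (any(sel)) {
      tb <- tabulate(sp$neuron_id[sel], nbins = n_neurons)
      D[, b] <- tb / (window / 1000)
    }
  }
  structure(D, window = window, step = step, bin_times = starts,
            class = c("rate_matrix", "matrix"))
}

# deterministic non-negative initialization from the leading singular
# vectors (NNDSVD-style); negative parts folded in, zeros lifted to the mean
nndsvd_init <- function(D, k) {
  sv <- svd(D, nu = k, nv = k)
  B <- matrix(0, nrow(D), k)
  C <- matrix(0, k, ncol(D))
  for (j in seq_len(k)) {
    u <- sv$u[, j]; v <- sv$v[, j]; s <- sv$d[j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    np <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (np >= nn && np > 0) {
      B[, j] <- sqrt(s * np) * up / sqrt(sum(up^2))
      C[j, ] <- sqrt(s * np) * vp / sqrt(sum(vp^2))
    } else if (nn > 0) {
      B[, j] <- sqrt(s * nn) * un / sqrt(sum(un^2))
      C[j, ] <- sqrt(s * nn) * vn / sqrt(sum(vn^2))
    }
  }
  m <- mean(D)
  B[B == 0] <- m
  C[C == 0] <- m
  list(B = B, C = C)
}

#' Non-negative matrix factorization at fixed order
#'
#' Frobenius-norm NMF by multiplicative updates. The objective is
#' non-increasing across iterations; iteration stops when the relative
#' objective decrease falls below `tol`.
#'
#' @param D non-negative matrix (neurons x time bins).
#' @param k factorization order.
#' @param init `"nndsvd"` (deterministic) or `"random"`.
#' @param seed seed for random initialization.
#' @param max_iter,tol stopping rule.
#' @return list with `B` (neurons x k), `C` (k x bins), `rss`, `objective`
#'   trace and iteration count.
#' @export
nmf_fit <- function(D, k, init = c("nndsvd", "random"), seed = 1,
                    max_iter = 300, tol = 1e-5) {
  init <- match.arg(init)
  stopifnot(k >= 1, k < min(dim(D)), all(D >= 0))
  eps <- .Machine$double.eps
  if (init == "nndsvd") {
    st <- nndsvd_init(D, k)
    B <- st$B; C <- st$C
  } else {
    set.seed(seed)
    m <- mean(D)
    B <- matrix(runif(nrow(D) * k, 0, 2 * m), nrow(D), k)
    C <- matrix(runif(k * ncol(D), 0, 2 * m), k, ncol(D))
  }
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    C <- C * (crossprod(B, D) / (crossprod(B) %*% C + eps))
    B <- B * (tcrossprod(D, C) / (B %*% tcrossprod(C) + eps))
    rss <- sum((D - B %*% C)^2)
    obj <- c(obj, rss)
    if (is.finite(prev) && (prev - rss) <= tol * prev) break
    prev <- rss
  }
  list(B = B, C = C, rss = rss, objective = obj, iterations = it)
}

# AICc variants; K counts all factor entries as free parameters.
# gaussian: n ln(RSS/n) + 2K + 2K(K+1)/(n-K-1).
# poisson: -2 loglik of the window spike counts at the fitted means
# (n! terms dropped: constant across orders).
aicc_nmf <- function(rss, n, K) {
  if (n - K - 1 <= 0) return(NA_real_)
  n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

aicc_nmf_poisson <- function(counts, mu, n, K) {
  if (n - K - 1 <= 0) return(NA_real_)
  mu <- pmax(mu, 1e-12)
  ll <- sum(counts * log(mu) - mu)
  -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Select the NMF order by AICc
#'
#' Factorizes `D` at each order in `k_range` (best of a deterministic
#' initialization plus seeded random restarts) and selects the order
#' minimizing the small-sample-corrected Akaike criterion with
#' \eqn{K = k(rows + cols)} free parameters and `n` the number of matrix
#' entries. Two residual models are available:
#' \itemize{
#'   \item `"poisson"` (default): \eqn{-2\log L + 2K + 2K(K+1)/(n-K-1)}
#'     with a Poisson likelihood of the window spike counts at the fitted
#'     means. Spike-count noise has variance proportional to the mean; on
#'     such data a homoscedastic Gaussian criterion keeps absorbing noise
#'     components and runs to the top of any feasible order range.
#'   \item `"gaussian"`: \eqn{n\ln(RSS/n) + 2K + 2K(K+1)/(n-K-1)},
#'     appropriate for matrices with roughly constant noise variance.
#' }
#' Orders with \eqn{n - K - 1 \le 0} are excluded with a warning. Ties
#' break on lower RSS, then lower order.
#'
#' @param D non-negative matrix (or `rate_matrix`).
#' @param k_range integer vector of candidate orders.
#' @param restarts number of random restarts per order (>= 1) in addition
#'   to the deterministic initialization.
#' @param seed master seed for the restarts.
#' @param max_iter,tol passed to [nmf_fit()].
#' @param criterion residual model for the AICc, see Details.
#' @param count_scale factor converting entries of `D` to counts for the
#'   Poisson criterion; defaults to `window/1000` for a [build_rate_matrix()]
#'   result (entries are Hz) and 1 otherwise.
#' @return object of class `nmf_result` with `B`, `Cmat`, `k`, `rss`,
#'   `aicc_trace` (data.frame `k`, `aicc`, `rss`).
#' @export
select_nmf_order <- function(D, k_range = 1:12, restarts = 3, seed = 1,
                             max_iter = 300, tol = 1e-5,
                             criterion = c("poisson", "gaussian"),
                             count_scale = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(restarts >= 1, all(k_range >= 1), all(k_range < min(dim(D))))
  if (is.null(count_scale)) {
    w <- attr(D, "window")
    count_scale <- if (is.null(w)) 1 else w / 1000
  }
  n <- length(D)
  seeds <- derive_seeds(seed, length(k_range) * restarts)
  trace <- data.frame(k = k_range, aicc = NA_real_, rss = NA_real_)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    K <- k * (nrow(D) + ncol(D))
    if (n - K - 1 <= 0) {
      warning("order k = ", k, " excluded: n - K - 1 <= 0")
      next
    }
    best <- nmf_fit(D, k, init = "nndsvd", max_iter = max_iter, tol = tol)
    for (r in seq_len(restarts)) {
      f <- nmf_fit(D, k, init = "random",
                   seed = seeds[(i - 1) * restarts + r],
                   max_iter = max_iter, tol = tol)
      if (f$rss < best$rss) best <- f
    }
    fits[[i]] <- best
    trace$rss[i] <- best$rss
    trace$aicc[i] <- if (criterion == "gaussian") {
      aicc_nmf(best$rss, n, K)
    } else {
      aicc_nmf_poisson(unclass(D) * count_scale,
                       best$B %*% best$C * count_scale, n, K)
    }
  }
  ok <- which(is.finite(trace$aicc))
  if (!length(ok)) stop("no admissible order in k_range")
  sel <- ok[order(trace$aicc[ok], trace$rss[ok], trace$k[ok])][1]
  out <- list(B = fits[[sel]]$B, Cmat = fits[[sel]]$C, k = k_range[sel],
              rss = trace$rss[sel], aicc_trace = trace)
  class(out) <- "nmf_result"
  out
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("NMF: selected order k = %d (AICc %.1f, RSS %.3g)\n", x$k,
              x$aicc_trace$aicc[x$aicc_trace$k == x$k], x$rss))
  invisible(x)
}

#' Correlate NMF order with UP-state duration across conditions
#'
#' Pearson correlation between the selected NMF order (and the order
#' normalized by the total UP-state duration) and the logarithm of the mean
#' transient-UP duration, across simulated conditions.
#'
#' @param orders integer vector of selected orders, one per condition.
#' @param mean_up_ms mean UP durations (ms) per condition.
#' @param total_up_ms total UP-state durations (ms) per condition, for the
#'   normalized order; defaults to `mean_up_ms` scaling only.
#' @return list with `cor`, `p`, `cor_normalized`, `p_normalized`; entries
#'   are `NA` when an input is constant.
#' @export
assembly_statistics <- function(orders, mean_up_ms, total_up_ms = NULL) {
  stopifnot(length(orders) == length(mean_up_ms), length(orders) >= 3)
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(list(estimate = NA_real_,
                                              p.value = NA_real_))
    ct <- cor.test(x, y)
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  lu <- log(mean_up_ms)
  c1 <- safe_cor(orders, lu)
  out <- list(cor = c1$estimate, p = c1$p.value,
              cor_normalized = NA_real_, p_normalized = NA_real_)
  if (!is.null(total_up_ms)) {
    c2 <- safe_cor(orders / total_up_ms, lu)
    out$cor_normalized <- c2$estimate
    out$p_normalized <- c2$p.value
  }
  out
}

#' Mean pairwise correlation of pattern activations
#'
#' Average Pearson correlation over all unordered pairs of activation time
#' courses (rows of `Cmat`).
#'
#' @param result an `nmf_result` (or any list with a `Cmat`).
#' @return mean pairwise correlation, or `NA` when `k < 2`.
#' @export
pattern_activation_correlation <- function(result) {
  C <- result$Cmat
  if (is.null(C) || nrow(C) < 2) return(NA_real_)
  cm <- suppressWarnings(cor(t(C)))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

#' Match extracted basis patterns to ground-truth assemblies
#'
#' Greedy assignment of basis columns to truth columns by maximal cosine
#' similarity; used to verify planted-assembly recovery.
#'
#' @param B extracted basis (neurons x k).
#' @param truth ground-truth membership matrix (neurons x g), 0/1.
#' @return numeric vector (length `min(k, g)`) of cosine similarities of the
#'   matched pairs, best first.
#' @export
match_assemblies <- function(B, truth) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- ncol(B); g <- ncol(truth)
  S <- outer(seq_len(k), seq_len(g),
             Vectorize(function(i, j) cosine(B[, i], truth[, j])))
  S <- matrix(S, k, g)
  m <- min(k, g)
  sims <- numeric(m)
  for (r in seq_len(m)) {
    ij <- arrayInd(which.max(S), dim(S))
    sims[r] <- S[ij[1], ij[2]]
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  sims
}
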