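# Renyi entropies and generalized fractal dimensions from value-bin
# probability distributions, the fractal spectrum, and sliding
# fractal-dimension trajectories.

#' Value-bin probability distribution of a series
#'
#' Divides the value range `[v_min, v_max]` into `N = ceiling((v_max -
#' v_min) / delta_v)` bins of width `delta_v` (left-closed/right-open, final
#' bin closed so ties at `v_max` land in the last bin) and returns the bin
#' occupation probabilities `w_i = N_i / sum(N_i)`. For a uniformly sampled
#' series the count-based probabilities equal the time-based ones (time spent
#' in a bin divided by total time) exactly, which is the implemented
#' identity.
#'
#' @param series Numeric vector, length `>= 1`.
#' @param delta_v Bin width in the series' units, `> 0`.
#' @return Object of class `bin_distribution` with fields `v_min`, `v_max`,
#'   `delta_v`, `n_bins`, `counts`, `weights`.
#' @examples
#' bin_probabilities(c(0, 1, 0, 1), 0.5)$weights
#' @export
bin_probabilities <- function(series, delta_v) {
  series <- as.numeric(series)
  if (length(series) < 1L) stop("'series' must be non-empty", call. = FALSE)
  if (!is.numeric(delta_v) || length(delta_v) != 1L || is.na(delta_v) ||
      delta_v <= 0)
    stop("'delta_v' must be a single positive bin width", call. = FALSE)
  v_min <- min(series)
  v_max <- max(series)
  span <- v_max - v_min
  n_bins <- max(1L, as.integer(ceiling(span / delta_v - 1e-9)))
  idx <- pmin(floor((series - v_min) / delta_v) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(v_min = v_min, v_max = v_max, delta_v = delta_v,
                 n_bins = n_bins, counts = counts,
                 weights = counts / sum(counts)),
            class = "bin_distribution")
}

#' @export
print.bin_distribution <- function(x, ...) {
  cat(sprintf("<bin_distribution> %d bins of width %g on [%g, %g], %d occupied\n",
              x$n_bins, x$delta_v, x$v_min, x$v_max, sum(x$counts > 0)))
  invisible(x)
}

#' Renyi entropy of a bin distribution
#'
#' \eqn{E_q = \frac{1}{1-q} \log_2 \sum_i w_i^q} in bits, with the Shannon
#' form \eqn{E_1 = -\sum_i w_i \log_2 w_i} at `q = 1`. Zero-weight bins are
#' skipped at every order. `E_q` is continuous and non-increasing in `q`.
#'
#' @param dist A [bin_probabilities()] result, or a bare probability vector.
#' @param q Moment order (any real).
#' @return Entropy in bits.
#' @examples
#' renyi_entropy(rep(1 / 8, 8), q = 2) # log2(8) = 3 bits
#' @export
renyi_entropy <- function(dist, q) {
  w <- if (inherits(dist, "bin_distribution")) dist$weights else as.numeric(dist)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  w <- w[w > 0]
  if (abs(q - 1) < 1e-12) -sum(w * log2(w))
  else log2(sum(w^q)) / (1 - q)
}

# partition-sum exponent y(delta_v) = (1/(q-1)) log2 sum w^q = -E_q.
# At negative q near-empty bins dominate the sum, so bins with fewer than
# min_count samples are excluded there (variance control).
partition_exponent <- function(series, delta_v, q, neg_min_count = 2L) {
  d <- bin_probabilities(series, delta_v)
  counts <- d$counts
  if (q < 0) counts[counts < neg_min_count] <- 0L
  w <- counts[counts > 0] / sum(counts)
  if (length(w) == 0L) return(NA_real_)
  if (abs(q - 1) < 1e-12) sum(w * log2(w)) else log2(sum(w^q)) / (q - 1)
}

#' Generalized (Renyi) fractal dimension of a series' value distribution
#'
#' Estimates \eqn{\aleph_q}, the scaling exponent of the order-q partition
#' sum of value-bin probabilities as the bin size shrinks: the least-squares
#' slope of \eqn{\frac{1}{q-1}\log_2\sum_i w_i(\delta V)^q} against
#' \eqn{\log_2 \delta V} over the supplied scale grid (Shannon numerator at
#' `q = 1`). A constant series occupies a single bin at every scale and has
#' dimension 0 with an undefined fit.
#'
#' @param series Numeric vector, length `>= 64` for a meaningful estimate.
#' @param q Moment order.
#' @param delta_v_grid Bin widths; at least 4 scales spanning at least 2
#'   octaves. Defaults to [auto_delta_v_grid()] of the series.
#' @return List of class `dimension_fit`: `dimension`, `r2`, `q`,
#'   `delta_v_grid`.
#' @export
generalized_dimension <- function(series, q, delta_v_grid = NULL) {
  series <- as.numeric(series)
  if (is.null(delta_v_grid)) delta_v_grid <- auto_delta_v_grid(series)
  if (diff(range(series)) == 0)
    return(structure(list(dimension = 0, r2 = NA_real_, q = q,
                          delta_v_grid = delta_v_grid),
                     class = "dimension_fit"))
  if (length(delta_v_grid) < 4L ||
      max(delta_v_grid) / min(delta_v_grid) < 4 - 1e-9)
    stop("'delta_v_grid' needs >= 4 scales spanning >= 2 octaves", call. = FALSE)
  y <- vapply(delta_v_grid, function(d) partition_exponent(series, d, q),
              numeric(1L))
  keep <- is.finite(y)
  if (sum(keep) < 3L || diff(range(y[keep])) == 0)
    return(structure(list(dimension = 0, r2 = NA_real_, q = q,
                          delta_v_grid = delta_v_grid),
                     class = "dimension_fit"))
  fit <- fit_loglog(log2(delta_v_grid[keep]), y[keep])
  structure(list(dimension = fit$slope, r2 = fit$r2, q = q,
                 delta_v_grid = delta_v_grid),
            class = "dimension_fit")
}

#' @export
print.dimension_fit <- function(x, ...) {
  cat(sprintf("<dimension_fit> q = %g: dimension = %.4f (R^2 = %.4f)\n",
              x$q, x$dimension, x$r2))
  invisible(x)
}

#' Automatic bin-size grid for dimension estimation
#'
#' Geometric bin widths between half the value range and range/256,
#' truncated so the finest grid still averages at least 2 samples per bin.
#'
#' @param series Numeric vector.
#' @param max_octaves Deepest scale as a power of two of the range.
#' @return Numeric vector of bin widths (coarse to fine).
#' @export
auto_delta_v_grid <- function(series, max_octaves = 8L) {
  r <- diff(range(series))
  if (r == 0) r <- 1
  n <- length(series)
  octs <- seq_len(max_octaves)
  octs <- octs[2^octs <= max(4, n / 2)]
  r / 2^octs
}

#' Fractal spectrum of a series
#'
#' Generalized dimensions over a grid of orders q, plus the spectrum range
#' \eqn{\aleph_{q_{min}} - \aleph_{q_{max}}} (a finite-grid stand-in for
#' \eqn{\aleph_{-\infty} - \aleph_{\infty}}). A wide range marks a
#' multifractal series; a self-similar series has equal dimensions at every
#' order and zero range. Entropies `E_q` are reported at the finest bin
#' width of the grid.
#'
#' @param series Numeric vector.
#' @param q_grid Orders; default -10..10 step 1 (|q| capped at 10 because
#'   negative-q moments are dominated by near-empty bins).
#' @param delta_v_grid Bin widths; default [auto_delta_v_grid()].
#' @return Object of class `renyi_spectrum` with fields `q_grid`,
#'   `dimensions`, `entropies`, `fit_r2`, `delta_v_grid`, `spectrum_range`.
#' @export
fractal_spectrum <- function(series, q_grid = -10:10, delta_v_grid = NULL) {
  series <- as.numeric(series)
  if (is.null(delta_v_grid)) delta_v_grid <- auto_delta_v_grid(series)
  fits <- lapply(q_grid, function(q)
    generalized_dimension(series, q, delta_v_grid))
  dims <- vapply(fits, `[[`, numeric(1L), "dimension")
  r2 <- vapply(fits, `[[`, numeric(1L), "r2")
  finest <- bin_probabilities(series, min(delta_v_grid))
  ent <- vapply(q_grid, function(q) renyi_entropy(finest, q), numeric(1L))
  structure(list(q_grid = q_grid, dimensions = dims, entropies = ent,
                 fit_r2 = r2, delta_v_grid = delta_v_grid,
                 spectrum_range = dims[[1L]] - dims[[length(dims)]]),
            class = "renyi_spectrum")
}

#' @export
print.renyi_spectrum <- function(x, ...) {
  cat(sprintf("<renyi_spectrum> q in [%g, %g], range %.4f\n",
              min(x$q_grid), max(x$q_grid), x$spectrum_range))
  invisible(x)
}

#' @export
as.data.frame.renyi_spectrum <- function(x, ...) {
  data.frame(q = x$q_grid, entropy_bits = x$entropies,
             dimension = x$dimensions, r2 = x$fit_r2)
}

#' Renyi box dimension of a signal's graph
#'
#' The fractal dimension of a signal as a curve: the window is integrated
#' (cumulative mean-adjusted sum), both axes are normalised to the unit
#' square, and the graph is covered by N x N boxes for a dyadic grid of N.
#' Per time column the trace sweeps a run of boxes; occupation weights are
#' spread uniformly over that run, and the order-q Renyi partition exponent
#' is regressed against `log2` box size. For self-affine traces this
#' dimension is approximately `2 - H`, so it rises when the signal becomes
#' more complex - the behaviour expected of the fractal-dimension channel.
#' A window with zero range returns 0 (degenerate, all occupation in one
#' value bin).
#'
#' @param series Numeric window.
#' @param q Moment order (default 1, the information dimension).
#' @param n_grid Dyadic grid of box counts per axis.
#' @return Dimension estimate (a scalar; about 1 for smooth traces, up to 2
#'   for rough ones).
#' @export
graph_dimension <- function(series, q = 1, n_grid = 2^(2:6)) {
  y <- cumsum(series - mean(series))
  r <- diff(range(y))
  if (r < 1e-12) return(0)
  y <- (y - min(y)) / r
  n <- length(y)
  lg <- vapply(n_grid, function(N) {
    col <- ceiling(seq_len(n) / n * N)
    mn <- tapply(y, col, min)
    mx <- tapply(y, col, max)
    cnt <- floor(mx * N - 1e-9) - floor(mn * N) + 1
    cnt[cnt < 1] <- 1
    nt <- length(cnt)
    if (abs(q - 1) < 1e-12) -(log2(nt) + mean(log2(cnt)))
    else log2(nt^(-q) * sum(cnt^(1 - q))) / (q - 1)
  }, numeric(1L))
  fit_loglog(log2(1 / n_grid), lg)$slope
}

#' Sliding-window fractal-dimension trajectory
#'
#' Computes a per-window fractal dimension along one channel. The default
#' measure (`fd_measure = "graph"`) is the Renyi box dimension of the
#' window's integrated profile ([graph_dimension()]), which tracks signal
#' complexity (approximately `2 - H`) and therefore deflects upward at a
#' persistence-breaking precursor. `fd_measure = "value"` instead uses the
#' value-binning [generalized_dimension()] of the raw window; note that it
#' is a function of the window's marginal value distribution only, so it
#' does not respond to purely temporal (correlation) changes.
#'
#' @inheritParams sliding_hurst
#' @param q Moment order of the per-window dimension.
#' @param fd_measure `"graph"` (default) or `"value"`.
#' @return A [trajectory()] with nonnegative values, of length
#'   `floor((T - window_s) / step_s) + 1`.
#' @export
sliding_fd <- function(record, channel = select_dominant_channel(record),
                       window_s = 10, step_s = 1, q = 1,
                       fd_measure = c("graph", "value"), mode = "sliding") {
  fd_measure <- match.arg(fd_measure)
  fn <- if (fd_measure == "graph") function(w) graph_dimension(w, q = q)
        else function(w) generalized_dimension(w, q = q)$dimension
  sliding_apply(record, channel, window_s, step_s, fn,
                measure_name = paste0("fd_", fd_measure), mode = mode)
}
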