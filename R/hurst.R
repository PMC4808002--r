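# Hurst exponent estimation: rescaled-range (R/S) analysis, a DFA
# cross-check, and sliding-window trajectories.

geom_scales <- function(n, min_scale, n_scales) {
  if (n < 2 * min_scale)
    stop("series too short: need length >= 2 * min_scale", call. = FALSE)
  unique(round(exp(seq(log(min_scale), log(n / 2), length.out = n_scales))))
}

fit_loglog <- function(log_x, log_y) {
  fit <- stats::lm.fit(cbind(1, log_x), log_y)
  slope <- fit$coefficients[[2L]]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log_y - mean(log_y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = slope, r2 = r2)
}

# mean rescaled range over non-overlapping segments of length s;
# segment S uses the divisor-n standard deviation.
rs_statistic <- function(series, s) {
  m <- floor(length(series) / s)
  X <- matrix(series[seq_len(m * s)], nrow = s)
  Xc <- sweep(X, 2L, colMeans(X))
  cs <- apply(Xc, 2L, cumsum)
  if (m == 1L) cs <- matrix(cs, ncol = 1L)
  R <- apply(cs, 2L, function(u) max(u) - min(u))
  S <- sqrt(colMeans(Xc^2))
  ok <- S > 0
  if (!any(ok)) return(NA_real_)
  mean(R[ok] / S[ok])
}

# Anis-Lloyd / Peters expected R/S of white noise at segment length n.
expected_rs <- function(n) {
  i <- seq_len(n - 1L)
  s <- sum(sqrt((n - i) / i))
  if (n <= 340) ((n - 0.5) / n) * exp(lgamma((n - 1) / 2) - lgamma(n / 2)) /
      sqrt(pi) * s
  else ((n - 0.5) / n) * s / sqrt(n * pi / 2)
}

#' Hurst exponent by rescaled-range analysis
#'
#' H is the least-squares slope of `log2(mean R/S at scale)` against
#' `log2(scale)` over geometrically spaced segment lengths from `min_scale`
#' to half the series length. Within each segment the rescaled range is the
#' range of the cumulative mean-adjusted sums divided by the segment's
#' divisor-n standard deviation. Estimates outside (0, 1) are clamped and
#' flagged (finite-sample R/S on trends can exceed 1).
#'
#' `correction = "anis-lloyd"` subtracts the slope of the Anis-Lloyd/Peters
#' expected white-noise R/S over the same scales and re-centres at 0.5. It
#' removes the well-known small-sample bias near H = 0.5 but overcorrects
#' strongly persistent series, so the plain slope is the default.
#'
#' @param series Numeric vector, length `>= 2 * min_scale`, not constant.
#' @param min_scale Smallest segment length.
#' @param n_scales Number of geometrically spaced scales.
#' @param correction `"none"` (default) or `"anis-lloyd"`.
#' @return A list of class `hurst_fit`: `h`, `r2`, `clamped`, `scales`,
#'   `rs` (mean R/S per scale), `method`.
#' @examples
#' rs_hurst(gen_fgn(2048, 0.7, seed = 1))$h
#' @export
rs_hurst <- function(series, min_scale = 8, n_scales = 12,
                     correction = c("none", "anis-lloyd")) {
  correction <- match.arg(correction)
  series <- as.numeric(series)
  if (stats::sd(series) == 0)
    stop("degenerate input: series is constant (zero deviation)", call. = FALSE)
  scales <- geom_scales(length(series), min_scale, n_scales)
  rs <- vapply(scales, function(s) rs_statistic(series, s), numeric(1L))
  keep <- is.finite(rs) & rs > 0
  fit <- fit_loglog(log2(scales[keep]), log2(rs[keep]))
  h <- fit$slope
  if (correction == "anis-lloyd") {
    th <- fit_loglog(log2(scales[keep]),
                     log2(vapply(scales[keep], expected_rs, numeric(1L))))
    h <- 0.5 + h - th$slope
  }
  clamped <- h <= 0 || h >= 1
  h <- min(max(h, 1e-6), 1 - 1e-6)
  structure(list(h = h, r2 = fit$r2, clamped = clamped, scales = scales[keep],
                 rs = rs[keep], method = paste0("rs", if (correction != "none")
                   paste0("+", correction))),
            class = "hurst_fit")
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' Standard DFA: the series is integrated (cumulative mean-adjusted sum),
#' split into non-overlapping windows per scale, polynomial-detrended within
#' each window, and the slope of `log2(rms fluctuation)` versus `log2(scale)`
#' is the scaling exponent (equal to H for stationary fGn-like signals).
#'
#' @inheritParams rs_hurst
#' @param order Polynomial detrending order per window.
#' @return A list of class `hurst_fit` (see [rs_hurst()]); element `rs` holds
#'   the fluctuation function.
#' @export
dfa_hurst <- function(series, min_scale = 8, n_scales = 12, order = 1) {
  series <- as.numeric(series)
  if (stats::sd(series) == 0)
    stop("degenerate input: series is constant (zero deviation)", call. = FALSE)
  n <- length(series)
  scales <- geom_scales(n, min_scale, n_scales)
  y <- cumsum(series - mean(series))
  fluct <- vapply(scales, function(s) {
    m <- floor(n / s)
    Y <- matrix(y[seq_len(m * s)], nrow = s)
    X <- stats::poly(seq_len(s), degree = order, raw = FALSE)
    Q <- qr.Q(qr(cbind(1, X)))
    res <- Y - Q %*% crossprod(Q, Y)
    sqrt(mean(res^2))
  }, numeric(1L))
  keep <- is.finite(fluct) & fluct > 0
  fit <- fit_loglog(log2(scales[keep]), log2(fluct[keep]))
  h <- fit$slope
  clamped <- h <= 0 || h >= 1
  h <- min(max(h, 1e-6), 1 - 1e-6)
  structure(list(h = h, r2 = fit$r2, clamped = clamped, scales = scales[keep],
                 rs = fluct[keep], method = sprintf("dfa%d", order)),
            class = "hurst_fit")
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf("<hurst_fit %s> H = %.4f (R^2 = %.4f%s)\n", x$method, x$h, x$r2,
              if (isTRUE(x$clamped)) ", clamped" else ""))
  invisible(x)
}

#' Construct a trajectory
#'
#' A time-indexed series of sliding-window values of a scalar measure.
#' `times` are window centres with constant spacing `step_s`.
#'
#' @param times Window-centre times in seconds, strictly increasing.
#' @param values Measure values (NA for flagged/degenerate windows).
#' @param window_s,step_s Window length and step in seconds (`window_s = 0`
#'   for trajectories not derived from sliding windows).
#' @param measure_name Label, e.g. `"hurst"` or `"fd"`.
#' @param flags Optional logical vector marking degenerate windows.
#' @return An object of class `trajectory` backed by a data frame with
#'   columns `time_s`, `value`, `flag`.
#' @export
trajectory <- function(times, values, window_s = 0, step_s = NA_real_,
                       measure_name = "measure", flags = NULL) {
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (is.null(flags)) flags <- rep(FALSE, length(values))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 window_s = window_s, step_s = step_s,
                 measure_name = measure_name, flags = flags),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s> %d points, window %g s, step %g s\n",
              x$measure_name, length(x$times), x$window_s, x$step_s))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, flag = x$flags)
}

# shared sliding-window driver; fn maps a numeric window to a scalar (or NA).
sliding_apply <- function(record, channel, window_s, step_s, fn,
                          measure_name, mode = c("sliding", "expanding")) {
  assert_record(record)
  mode <- match.arg(mode)
  if (window_s > record$T)
    stop("'window_s' (", window_s, " s) exceeds record duration (",
         record$T, " s)", call. = FALSE)
  ws <- round(window_s * record$fs)
  ss <- round(step_s * record$fs)
  if (ws < 64) stop("window must contain at least 64 samples", call. = FALSE)
  x <- record$data[channel, ]
  starts <- seq(1L, length(x) - ws + 1L, by = ss)
  vals <- vapply(starts, function(i) {
    w <- if (mode == "sliding") x[i:(i + ws - 1L)] else x[seq_len(i + ws - 1L)]
    out <- tryCatch(fn(w), error = function(e) NA_real_)
    if (is.finite(out)) out else NA_real_
  }, numeric(1L))
  trajectory(times = (starts - 1L) / record$fs + window_s / 2, values = vals,
             window_s = window_s, step_s = step_s, measure_name = measure_name,
             flags = !is.finite(vals))
}

#' Sliding-window Hurst trajectory
#'
#' Applies [rs_hurst()] (or [dfa_hurst()]) to successive windows of one
#' channel. Degenerate windows yield a flagged `NA`, not an error. With
#' `mode = "expanding"` the window start stays at the record start and the
#' end advances, matching an initial-estimate-then-update analysis.
#'
#' @param record An [eeg_record()].
#' @param channel Channel index (default: the dominant channel).
#' @param window_s,step_s Window length and step in seconds
#'   (`window_s * fs >= 64`).
#' @param method `"rs"` or `"dfa"`.
#' @param mode `"sliding"` (default) or `"expanding"`.
#' @param ... Passed to the estimator.
#' @return A [trajectory()] with values in (0, 1), of length
#'   `floor((T - window_s) / step_s) + 1`.
#' @export
sliding_hurst <- function(record, channel = select_dominant_channel(record),
                          window_s = 10, step_s = 1,
                          method = c("rs", "dfa"), mode = "sliding", ...) {
  method <- match.arg(method)
  est <- if (method == "rs") function(w) rs_hurst(w, ...)$h
         else function(w) dfa_hurst(w, ...)$h
  sliding_apply(record, channel, window_s, step_s, est,
                measure_name = paste0("hurst_", method), mode = mode)
}
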