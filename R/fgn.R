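# Fractional Gaussian noise synthesis.
#
# fGn is the canonical stationary process with a controllable Hurst exponent,
# which makes it the natural generative model for signals whose long-range
# dependence the estimators in this package are meant to recover.

#' Autocovariance of fractional Gaussian noise
#'
#' Autocovariance \eqn{\gamma(k) = \frac{1}{2}(|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})} of unit-variance fGn with Hurst exponent `h`.
#'
#' @param k Integer lag(s), `k >= 0`.
#' @param h Hurst exponent in (0, 1).
#' @return Numeric vector of autocovariances, one per lag.
#' @examples
#' fgn_acov(0:3, 0.9)
#' fgn_acov(1, 0.5) # uncorrelated at H = 0.5
#' @export
fgn_acov <- function(k, h) {
  stopifnot(is.numeric(k), all(k >= 0))
  check_hurst_param(h)
  0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
}

check_hurst_param <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0 || h >= 1)
    stop("Hurst parameter 'h' must be a single value in (0, 1)", call. = FALSE)
  invisible(h)
}

#' Generate fractional Gaussian noise
#'
#' Samples a zero-mean, unit-variance stationary Gaussian series with Hurst
#' exponent `h` by circulant embedding (Davies-Harte spectral synthesis).
#' When the circulant embedding of the autocovariance is not nonnegative
#' definite, the generator falls back to sequential conditional simulation
#' (Hosking's Durbin-Levinson recursion), which is exact for any valid
#' autocovariance but costs O(n^2).
#'
#' @param n Number of samples, `n >= 2`.
#' @param h Hurst exponent in (0, 1). `h = 0.5` gives white noise; `h > 0.5`
#'   persistent, `h < 0.5` anti-persistent correlations.
#' @param seed Optional integer seed; identical `(n, h, seed)` calls return
#'   bitwise-identical series.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_fgn(1024, 0.9, seed = 1)
#' cor(x[-1], x[-1024]) # near 2^(2*0.9-1) - 1
#' @export
gen_fgn <- function(n, h, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  check_hurst_param(h)
  if (!is.null(seed)) set.seed(seed)

  g <- fgn_acov(0:n, h)
  # circulant first row of length 2n: gamma(0..n-1), gamma(n), gamma(n-1..1)
  ev <- Re(stats::fft(c(g[1:n], g[n + 1L], g[n:2])))
  if (min(ev) < -1e-8 * max(ev)) return(fgn_hosking(n, h, g))
  ev[ev < 0] <- 0
  m <- 2L * n
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  # real part of the synthesized circulant process has exactly the target
  # autocovariance when the eigenvalue amplitudes are sqrt(ev / m)
  Re(stats::fft(sqrt(ev / m) * z))[1:n]
}

# Durbin-Levinson sequential-conditional fallback; g = acov at lags 0..n,
# so gamma(l) = g[l + 1].
fgn_hosking <- function(n, h, g = fgn_acov(0:n, h)) {
  x <- numeric(n)
  phi <- numeric(0)
  v <- g[1L]
  x[1L] <- stats::rnorm(1L) * sqrt(v)
  for (k in seq_len(n - 1L)) {
    if (k == 1L) {
      kappa <- g[2L] / g[1L]
      phi <- kappa
    } else {
      kappa <- (g[k + 1L] - sum(phi * g[k:2])) / v
      phi <- c(phi - kappa * rev(phi), kappa)
    }
    v <- v * (1 - kappa^2)
    mu <- sum(phi * x[k:1])
    x[k + 1L] <- mu + stats::rnorm(1L) * sqrt(v)
  }
  x
}
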