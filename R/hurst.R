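# Decimated orthonormal Haar transform: detail coefficients per octave.
# Odd-length remainders are dropped at each level.
haar_dwt <- function(x, j_max) {
  out <- vector("list", j_max)
  s <- x
  for (j in seq_len(j_max)) {
    m <- floor(length(s) / 2)
    if (m < 1) {
      out[[j]] <- numeric(0)
      next
    }
    a <- s[2 * seq_len(m) - 1]
    b <- s[2 * seq_len(m)]
    out[[j]] <- (a - b) / sqrt(2)
    s <- (a + b) / sqrt(2)
  }
  out
}

# Squared gain of the equivalent level-j Haar detail filter on a midpoint
# frequency grid over (0, 1/2); |H(f)|^2 = 2 cos^2(pi f), |G(f)|^2 =
# 2 sin^2(pi f), G_j(f) = G(2^(j-1) f) prod_k H(2^k f). Cached per process.
.hurst_cache <- new.env(parent = emptyenv())

haar_gain_grid <- function(j_max, n_grid = 8192) {
  key <- sprintf("g_%d_%d", j_max, n_grid)
  if (!is.null(.hurst_cache[[key]])) return(.hurst_cache[[key]])
  f <- (seq_len(n_grid) - 0.5) / (2 * n_grid)
  gains <- matrix(0, nrow = j_max, ncol = n_grid)
  low_prod <- rep(1, n_grid)
  for (j in seq_len(j_max)) {
    gains[j, ] <- 2 * sin(pi * 2^(j - 1) * f)^2 * low_prod
    low_prod <- low_prod * 2 * cos(pi * 2^(j - 1) * f)^2
  }
  res <- list(f = f, gains = gains)
  .hurst_cache[[key]] <- res
  res
}

# Model variance of level-j detail coefficients for a fractionally
# integrated process with unit innovation variance: the integral of
# |2 sin(pi f)|^(-2d) against the squared detail-filter gain.
fip_scale_factors <- function(d, levels, grid) {
  base <- abs(2 * sin(pi * grid$f))^(-2 * d)
  vapply(levels, function(j) mean(base * grid$gains[j, ]), 0)
}

#' Configuration of the wavelet maximum-likelihood Hurst estimator
#'
#' @param wavelet Wavelet filter; only `"haar"` is implemented.
#' @param d_bounds Box for the memory parameter d (H = d + 1/2); the default
#'   `c(-0.5, 1.5)` admits non-stationary series up to H = 2.
#' @param scale_bounds Box for the innovation-variance-like scale parameter.
#' @param j_min Finest octave used (the finest octave j = 1 is dropped by
#'   default to limit discretization bias).
#' @param j_max Coarsest octave; default `floor(log2(n)) - 3` so every used
#'   octave retains at least 8 coefficients.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(wavelet = "haar", d_bounds = c(-0.5, 1.5),
                             scale_bounds = c(0, 10), j_min = 2,
                             j_max = NULL) {
  if (!identical(wavelet, "haar")) stop("only the haar wavelet is implemented")
  if (d_bounds[1] >= d_bounds[2] || scale_bounds[1] >= scale_bounds[2]) {
    stop("lower bounds must be below upper bounds")
  }
  structure(list(wavelet = wavelet, d_bounds = d_bounds,
                 scale_bounds = scale_bounds, j_min = j_min, j_max = j_max),
            class = "estimator_config")
}

#' Hurst exponent by wavelet maximum likelihood under the FIP model
#'
#' Models the series as a fractionally integrated process whose spectral
#' density is proportional to `|2 sin(pi f)|^(-2d)` and maximizes the
#' Gaussian likelihood of the per-octave Haar detail coefficients
#' (independence across and within octaves assumed, the standard
#' wavelet-whitening approximation). The model variance at octave j is the
#' integral of the FIP spectral density against the squared gain of the
#' equivalent detail filter. The scale parameter is profiled out in closed
#' form; the memory parameter d is found by a deterministic grid multistart
#' refined with bounded 1-D optimization. H = d + 1/2, so white noise gives
#' H = 0.5 and a random walk H = 1.5; H > 1 indicates a non-stationary
#' series.
#'
#' @param series Numeric vector, finite and non-constant.
#' @param cfg An [estimator_config()].
#' @return An object of class `hurst_estimate`: `H`, `d`, `scale_param`,
#'   `n_scales`, `log_lik`, `converged` (FALSE when the optimizer sits on a
#'   bound or the profiled scale leaves its box; the estimate is still
#'   returned).
#' @export
estimate_hurst_fip <- function(series, cfg = estimator_config()) {
  x <- as.numeric(series)
  if (any(!is.finite(x))) stop("series contains non-finite values")
  n <- length(x)
  if (n < 2^(cfg$j_min + 2)) stop("series too short for the requested octaves")
  if (sd(x) == 0) stop("series is constant")
  j_max <- if (is.null(cfg$j_max)) floor(log2(n)) - 3 else cfg$j_max
  j_max <- max(j_max, cfg$j_min)
  levels <- seq(cfg$j_min, j_max)
  coeffs <- haar_dwt(x, j_max)
  m_j <- vapply(levels, function(j) mean(coeffs[[j]]^2), 0)
  n_j <- vapply(levels, function(j) length(coeffs[[j]]), 0L)
  if (any(n_j < 1)) stop("empty octave; reduce j_max")
  grid <- haar_gain_grid(j_max)
  n_tot <- sum(n_j)

  profile_sigma2 <- function(d) {
    c_j <- fip_scale_factors(d, levels, grid)
    sum(n_j * m_j / c_j) / n_tot
  }
  neg2ll <- function(d) {
    c_j <- fip_scale_factors(d, levels, grid)
    s2 <- sum(n_j * m_j / c_j) / n_tot
    sum(n_j * log(c_j)) + n_tot * log(s2) + n_tot
  }

  lb <- cfg$d_bounds[1] + 1e-4
  ub <- cfg$d_bounds[2] - 1e-4
  d_grid <- seq(lb, ub, length.out = 25)
  vals <- vapply(d_grid, neg2ll, 0)
  i0 <- which.min(vals)
  lo <- d_grid[max(1, i0 - 1)]
  hi <- d_grid[min(length(d_grid), i0 + 1)]
  opt <- optimize(neg2ll, lower = lo, upper = hi, tol = 1e-6)
  d_hat <- opt$minimum
  s2_hat <- profile_sigma2(d_hat)
  converged <- d_hat > lb + 1e-3 && d_hat < ub - 1e-3 &&
    s2_hat >= cfg$scale_bounds[1] && s2_hat <= cfg$scale_bounds[2]
  structure(list(H = d_hat + 0.5, d = d_hat,
                 scale_param = min(max(s2_hat, cfg$scale_bounds[1]),
                                   cfg$scale_bounds[2]),
                 n_scales = length(levels), log_lik = -opt$objective / 2,
                 converged = converged, cfg = cfg),
            class = "hurst_estimate")
}

#' Simulate a fractionally integrated process
#'
#' For `d < 0.5` draws a stationary ARFIMA(0, d, 0) realization by applying
#' the truncated fractional-integration moving-average filter to Gaussian
#' innovations (FFT convolution, full pre-history burn-in). For `d >= 0.5`
#' returns the cumulative sum of an ARFIMA(0, d - 1, 0) realization.
#'
#' @param d Memory parameter in the open interval (-0.5, 1.5).
#' @param n Series length, >= 16.
#' @param scale Innovation variance.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_fip <- function(d, n, scale = 1, seed = NULL) {
  if (d <= -0.5 || d >= 1.5) stop("d must lie in (-0.5, 1.5)")
  if (n < 16) stop("n must be at least 16")
  if (!is.null(seed)) set.seed(seed)
  if (d >= 0.5) {
    return(cumsum(arfima_stationary(d - 1, n, scale)))
  }
  arfima_stationary(d, n, scale)
}

# Exact stationary ARFIMA(0, d, 0) sample by Davies-Harte circulant
# embedding of the closed-form autocovariance
# gamma(0) = scale * Gamma(1 - 2d) / Gamma(1 - d)^2,
# rho(k) = rho(k - 1) * (k - 1 + d) / (k - d).
arfima_stationary <- function(d, n, scale) {
  if (abs(d) < 1e-12) {
    return(rnorm(n, 0, sqrt(scale)))
  }
  m <- stats::nextn(n, 2)
  g0 <- scale * gamma(1 - 2 * d) / gamma(1 - d)^2
  k <- seq_len(m)
  rho <- cumprod((k - 1 + d) / (k - d))
  gam <- g0 * c(1, rho)                       # gamma(0) .. gamma(m)
  circ <- c(gam, rev(gam[2:m]))               # circulant first row, length 2m
  lam <- Re(fft(circ))
  lam[lam < 0] <- 0                           # guard tiny negative rounding
  z <- (rnorm(2 * m) + 1i * rnorm(2 * m)) / sqrt(2)
  x <- Re(fft(sqrt(lam) * z)) / sqrt(m)
  x[seq_len(n)]
}

#' Sliding-window Hurst exponent
#'
#' Applies [estimate_hurst_fip()] to consecutive windows; with the default
#' window of 512 samples and step 1 this yields the dynamic H time course
#' used for windowed BOLD analyses.
#'
#' @param series Numeric vector with length >= `window`.
#' @param window Window length, samples.
#' @param step Step between window starts, samples.
#' @param cfg An [estimator_config()].
#' @return An object of class `windowed_hurst`: data frame `estimates` with
#'   `start` (1-based window start), `H`, `d`, `converged`, plus `window`
#'   and `step`.
#' @export
sliding_window_hurst <- function(series, window = 512, step = 1,
                                 cfg = estimator_config()) {
  n <- length(series)
  if (window > n) stop("window longer than the series")
  starts <- seq(1, n - window + 1, by = step)
  H <- numeric(length(starts))
  d <- numeric(length(starts))
  conv <- logical(length(starts))
  for (i in seq_along(starts)) {
    est <- estimate_hurst_fip(series[starts[i]:(starts[i] + window - 1)], cfg)
    H[i] <- est$H
    d[i] <- est$d
    conv[i] <- est$converged
  }
  structure(list(estimates = data.frame(start = starts, H = H, d = d,
                                        converged = conv),
                 window = window, step = step),
            class = "windowed_hurst")
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("<hurst_estimate> H = %.3f (d = %.3f, scale = %.3g, %d octaves%s)\n",
              x$H, x$d, x$scale_param, x$n_scales,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}
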