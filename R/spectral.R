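hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# One-sided periodogram of a (windowed, demeaned) segment; power normalized
# so that sum(psd) * df equals the segment variance (Parseval).
segment_psd <- function(x, rate, window) {
  n <- length(x)
  xw <- (x - mean(x)) * window
  sp <- abs(fft(xw))^2 / (rate * sum(window^2))
  n_keep <- floor(n / 2) + 1
  psd <- sp[seq_len(n_keep)]
  # fold negative frequencies onto positive ones (except DC and Nyquist)
  last <- if (n %% 2 == 0) n_keep - 1 else n_keep
  if (last >= 2) psd[2:last] <- 2 * psd[2:last]
  psd
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hamming-tapered, mean-removed, 50%-overlapping
#' segments. The default of ten segments with half overlap follows the
#' spectral analysis used for the simulated field potentials.
#'
#' @param series Numeric vector.
#' @param rate Sampling rate, Hz.
#' @param n_segments Number of overlapping segments.
#' @param overlap Fractional overlap between consecutive segments.
#' @return An object of class `psd_estimate` with `freqs` (Hz), `power`
#'   (units^2/Hz) and `meta` (segment length, count, overlap).
#' @export
welch_psd <- function(series, rate, n_segments = 10, overlap = 0.5) {
  n <- length(series)
  if (n < n_segments) stop("series shorter than the number of segments")
  seg_len <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  if (seg_len < 8) stop("series too short for one segment")
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  starts <- starts[seq_len(min(length(starts), n_segments))]
  win <- hamming_window(seg_len)
  acc <- 0
  for (s in starts) {
    acc <- acc + segment_psd(series[s:(s + seg_len - 1)], rate, win)
  }
  power <- acc / length(starts)
  freqs <- seq(0, length.out = length(power), by = rate / seg_len)
  structure(list(freqs = freqs, power = power,
                 meta = list(segment_length = seg_len,
                             n_segments = length(starts), overlap = overlap,
                             rate = rate)),
            class = "psd_estimate")
}

#' Piecewise 1/f slope fit
#'
#' Fits two independent least-squares lines to the PSD in log10-power versus
#' log10-frequency coordinates: one over the low-frequency range (default
#' 1-30 Hz) and one over the high-frequency range (default 30-100 Hz).
#'
#' @param psd A `psd_estimate`.
#' @param low,high Frequency ranges `c(f_lo, f_hi)` in Hz.
#' @return An object of class `slope_fit` with `slope_low`, `slope_high`,
#'   `r2_low`, `r2_high` and the ranges used.
#' @export
fit_piecewise_slopes <- function(psd, low = c(1, 30), high = c(30, 100)) {
  stopifnot(inherits(psd, "psd_estimate"))
  fit_range <- function(rng) {
    sel <- psd$freqs >= rng[1] & psd$freqs <= rng[2] & psd$power > 0
    if (sum(sel) < 3) {
      stop(sprintf("fewer than 3 PSD bins in [%g, %g] Hz", rng[1], rng[2]))
    }
    lx <- log10(psd$freqs[sel])
    ly <- log10(psd$power[sel])
    b <- cov(lx, ly) / var(lx)
    resid <- ly - (mean(ly) + b * (lx - mean(lx)))
    r2 <- if (var(ly) > 0) 1 - var(resid) / var(ly) else 1
    c(slope = b, r2 = r2)
  }
  lo <- fit_range(low)
  hi <- fit_range(high)
  structure(list(slope_low = unname(lo["slope"]),
                 slope_high = unname(hi["slope"]),
                 r2_low = unname(lo["r2"]), r2_high = unname(hi["r2"]),
                 low = low, high = high),
            class = "slope_fit")
}

#' Band-limited power time course
#'
#' Sliding-window spectrogram power integrated over a frequency band,
#' timestamped at window centers. Windows are Hamming-tapered and
#' mean-removed.
#'
#' @param series Numeric vector.
#' @param rate Sampling rate, Hz.
#' @param band `c(f_lo, f_hi)` in Hz; must lie below the Nyquist frequency.
#' @param window_s Window length, s.
#' @param step_s Step between window starts, s.
#' @return An object of class `band_power_series` with `times` (s, window
#'   centers), `power` (units^2) and `band`.
#' @export
band_power_timecourse <- function(series, rate, band, window_s = 1,
                                  step_s = 0.5) {
  if (band[2] > rate / 2) stop("band extends above the Nyquist frequency")
  if (band[1] > 0 && window_s < 2 / band[1]) {
    stop("window too short to resolve the lower band edge")
  }
  wlen <- round(window_s * rate)
  step <- max(1L, round(step_s * rate))
  n <- length(series)
  if (n < wlen) stop("series shorter than one window")
  starts <- seq(1, n - wlen + 1, by = step)
  win <- hamming_window(wlen)
  freqs <- seq(0, length.out = floor(wlen / 2) + 1, by = rate / wlen)
  sel <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  df <- rate / wlen
  power <- vapply(starts, function(s) {
    psd <- segment_psd(series[s:(s + wlen - 1)], rate, win)
    sum(psd[sel]) * df
  }, 0)
  structure(list(times = (starts - 1 + wlen / 2) / rate, power = power,
                 band = band,
                 meta = list(window_s = window_s, step_s = step_s, rate = rate)),
            class = "band_power_series")
}

#' Time-lagged correlation between LFP band power and BOLD
#'
#' Computes the band-power time course of the LFP for each requested band,
#' resamples it at the BOLD sampling instants by linear interpolation, and
#' reports the Pearson correlation with the BOLD series for every
#' non-negative lag (BOLD delayed relative to LFP power) up to `max_lag_s`,
#' together with the peak lag and peak correlation per band.
#'
#' @param lfp An `lfp_trace` (or aggregated trace) covering the same
#'   interval as `bold`.
#' @param bold A `bold_series`.
#' @param bands Named list of `c(f_lo, f_hi)` bands, Hz.
#' @param max_lag_s Maximum lag, s.
#' @param window_s,step_s Spectrogram parameters for the power time course.
#' @return An object of class `lag_correlation`: per band a data frame of
#'   `lag_s` and `r`, plus `peak` (data frame of band, peak lag, peak r).
#' @export
lagged_band_bold_correlation <- function(lfp, bold,
                                         bands = list(alpha = c(8, 12),
                                                      beta = c(15, 30),
                                                      gamma = c(40, 100),
                                                      total = c(0, 100)),
                                         max_lag_s = 10,
                                         window_s = 1, step_s = 0.5) {
  stopifnot(inherits(bold, "bold_series"))
  bold_t <- seq(0, length.out = length(bold$samples), by = 1 / bold$rate)
  lag_step <- 1 / bold$rate
  lags <- seq(0, max_lag_s, by = lag_step)
  curves <- list()
  peaks <- data.frame(band = names(bands), peak_lag_s = NA_real_,
                      peak_r = NA_real_)
  for (bi in seq_along(bands)) {
    bp <- band_power_timecourse(lfp$samples, lfp$rate, bands[[bi]],
                                window_s, step_s)
    p_at_bold <- approx(bp$times, bp$power, xout = bold_t, rule = 2)$y
    r <- rep(NA_real_, length(lags))
    for (li in seq_along(lags)) {
      k <- round(lags[li] / lag_step)
      n <- length(bold_t) - k
      if (n < 10) {
        warning(sprintf("lag %.2f s dropped: fewer than 10 overlapping samples",
                        lags[li]))
        next
      }
      x <- p_at_bold[seq_len(n)]
      y <- bold$samples[seq_len(n) + k]
      if (sd(x) == 0 || sd(y) == 0) next
      r[li] <- cor(x, y)
    }
    curves[[names(bands)[bi]]] <- data.frame(lag_s = lags, r = r)
    if (any(!is.na(r))) {
      best <- which.max(r)
      peaks$peak_lag_s[bi] <- lags[best]
      peaks$peak_r[bi] <- r[best]
    }
  }
  structure(list(curves = curves, peak = peaks, bands = bands),
            class = "lag_correlation")
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Ratio of the summed spectral amplitude (square root of the periodogram)
#' inside a low-frequency band to the summed amplitude over the total
#' detectable band. The DC bin is excluded; the default total band upper
#' edge is half the sampling rate of a 0.5 Hz BOLD series.
#'
#' @param bold A `bold_series`, or a numeric vector with `rate` given.
#' @param low_band,total_band `c(f_lo, f_hi)` in Hz.
#' @param rate Sampling rate, Hz (only when `bold` is a bare vector).
#' @return A single fraction in \[0, 1\].
#' @export
compute_falff <- function(bold, low_band = c(0.01, 0.08),
                          total_band = c(0, 0.25), rate = NULL) {
  if (inherits(bold, "bold_series")) {
    x <- bold$samples
    rate <- bold$rate
  } else {
    x <- as.numeric(bold)
    if (is.null(rate)) stop("rate must be given for a bare series")
  }
  if (rate < 2 * total_band[2]) {
    stop("sampling rate below twice the total band upper edge")
  }
  n <- length(x)
  # periodic Hamming taper: bin-centred tones occupy exactly three bins and
  # off-grid tones leak only into nearby bins
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / n)
  amp <- abs(fft((x - mean(x)) * w))[seq_len(floor(n / 2) + 1)]
  freqs <- seq(0, length.out = length(amp), by = rate / n)
  lo <- freqs > 0 & freqs >= low_band[1] & freqs <= low_band[2]
  tot <- freqs > 0 & freqs >= total_band[1] & freqs <= total_band[2]
  if (!any(lo) || !any(tot)) stop("empty frequency band")
  sum(amp[lo]) / sum(amp[tot])
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%.4g Hz (%d segments)\n",
              length(x$freqs), max(x$freqs), x$meta$n_segments))
  invisible(x)
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> low [%g-%g Hz]: %.3f (R2 %.2f); high [%g-%g Hz]: %.3f (R2 %.2f)\n",
    x$low[1], x$low[2], x$slope_low, x$r2_low,
    x$high[1], x$high[2], x$slope_high, x$r2_high))
  invisible(x)
}
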