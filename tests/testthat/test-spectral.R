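df_of <- function(p) p$freqs[2] - p$freqs[1]

test_that("Welch PSD locates line spectra and conserves variance", {
  t <- seq(0, 10, by = 1e-3)[-1]
  x <- sin(2 * pi * 10 * t)
  psd <- welch_psd(x, 1000)
  df <- psd$freqs[2] - psd$freqs[1]
  expect_lt(abs(psd$freqs[which.max(psd$power)] - 10), df)
  # Parseval on white noise
  set.seed(8)
  w <- rnorm(20000, sd = 2)
  pw <- welch_psd(w, 1000)
  expect_lt(abs(sum(pw$power) * df_of(pw) - var(w)) / var(w), 0.05)
  # two sinusoids: two peaks, additive power
  y <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 40 * t)
  py <- welch_psd(y, 1000)
  tot <- sum(py$power) * df_of(py)
  expect_lt(abs(tot - (0.5 + 0.125)) / 0.625, 0.05)
  hi_band <- py$freqs >= 25 & py$freqs <= 60
  f40 <- py$freqs[hi_band][which.max(py$power[hi_band])]
  expect_lt(abs(f40 - 40), df_of(py))
  expect_error(welch_psd(rnorm(5), 1000), "short")
})

test_that("piecewise slope fit is exact on synthetic power laws", {
  f <- seq(0.5, 500, by = 0.5)
  mk_psd <- function(p) structure(list(freqs = f, power = p, meta = list()),
                                  class = "psd_estimate")
  s <- fit_piecewise_slopes(mk_psd(f^-2))
  expect_equal(s$slope_low, -2, tolerance = 1e-10)
  expect_equal(s$slope_high, -2, tolerance = 1e-10)
  # broken power law, continuous at 30 Hz
  p <- ifelse(f <= 30, f^-0.5, 30^(-0.5 + 3) * f^-3)
  s2 <- fit_piecewise_slopes(mk_psd(p))
  expect_equal(s2$slope_low, -0.5, tolerance = 1e-6)
  expect_equal(s2$slope_high, -3, tolerance = 1e-6)
  s3 <- fit_piecewise_slopes(mk_psd(rep(2.5, length(f))))
  expect_equal(s3$slope_low, 0, tolerance = 1e-10)
  expect_equal(s3$slope_high, 0, tolerance = 1e-10)
  # invariance to positive rescaling of the PSD
  s4 <- fit_piecewise_slopes(mk_psd(1e6 * f^-2))
  expect_equal(s4$slope_low, -2, tolerance = 1e-10)
  expect_error(fit_piecewise_slopes(mk_psd(f^-2), low = c(499.6, 500)), "bins")
})

test_that("band power time course tracks a modulation envelope", {
  t <- seq(0, 20, by = 1e-3)[-1]
  env <- 1 + 0.8 * sin(2 * pi * 0.2 * t)
  x <- env * sin(2 * pi * 60 * t)
  bp <- band_power_timecourse(x, 1000, c(40, 100))
  env_at <- 1 + 0.8 * sin(2 * pi * 0.2 * bp$times)
  expect_gt(cor(bp$power, env_at^2), 0.95)
  # out-of-band rejection: a pure 10 Hz tone leaves the gamma band empty
  tone <- sin(2 * pi * 10 * t)
  g <- band_power_timecourse(tone, 1000, c(40, 100))
  a <- band_power_timecourse(tone, 1000, c(8, 12))
  expect_lt(mean(g$power), 0.01 * mean(a$power))
  # stationary noise: windowed mean consistent with the whole-series PSD
  set.seed(10)
  w <- rnorm(20000)
  bw <- band_power_timecourse(w, 1000, c(20, 80))
  psd <- welch_psd(w, 1000)
  sel <- psd$freqs >= 20 & psd$freqs <= 80
  whole <- sum(psd$power[sel]) * df_of(psd)
  expect_lt(abs(mean(bw$power) - whole) / whole, 0.1)
  expect_error(band_power_timecourse(w, 1000, c(100, 600)), "Nyquist")
})

test_that("lagged band-BOLD correlation finds a planted shift and rejects noise", {
  set.seed(12)
  n <- 120
  base <- abs(rnorm(n)) + 1
  # gamma carrier whose amplitude follows a step envelope; BOLD equal to the
  # band power shifted by one sample peaks at that lag with r near 1
  carrier <- sin(2 * pi * 60 * seq_len(240000) / 1000)
  lfp_like <- lfp_trace(rep(base, each = 2000)[1:240000] * carrier, 1000)
  bp <- band_power_timecourse(lfp_like$samples, 1000, c(0, 100), 2, 2)
  shift <- 2
  # delay the BOLD by two samples relative to the band power
  bold <- bold_series(c(rep(bp$power[1], shift),
                        bp$power[seq_len(length(bp$power) - shift)]),
                      rate = 0.5)
  lc <- lagged_band_bold_correlation(lfp_like, bold,
                                     bands = list(total = c(0, 100)),
                                     max_lag_s = 10, window_s = 2, step_s = 2)
  # peak within one BOLD sample of the planted delay (window-center
  # timestamps blur the alignment by up to half a window)
  expect_lte(abs(lc$peak$peak_lag_s[1] - shift * 2), 2)
  expect_gt(lc$peak$peak_r[1], 0.7)
  # independent white-noise BOLD: small peak correlation
  rs <- replicate(20, {
    b2 <- bold_series(rnorm(n), 0.5)
    lagged_band_bold_correlation(lfp_like, b2,
                                 bands = list(total = c(0, 100)),
                                 max_lag_s = 10, window_s = 2,
                                 step_s = 2)$peak$peak_r[1]
  })
  expect_gt(mean(abs(rs) < 0.35), 0.9)
})

test_that("fALFF behaves as an in-band amplitude fraction", {
  tt <- seq(0, by = 2, length.out = 512)
  df <- 0.5 / 512
  f_lo <- 31 * df   # ~0.0303 Hz, on the bin grid
  f_hi <- 205 * df  # ~0.2002 Hz, on the bin grid
  expect_gt(compute_falff(sin(2 * pi * f_lo * tt), rate = 0.5), 0.99)
  expect_lt(compute_falff(sin(2 * pi * f_hi * tt), rate = 0.5), 0.01)
  fw <- sapply(1:50, function(s) { set.seed(s); compute_falff(rnorm(512), rate = 0.5) })
  expect_lt(abs(mean(fw) - 0.07 / 0.25), 0.05)
  # moving power from high to low frequencies raises fALFF
  lo <- compute_falff(sin(2 * pi * f_lo * tt) + 0.2 * sin(2 * pi * f_hi * tt),
                      rate = 0.5)
  hi <- compute_falff(0.2 * sin(2 * pi * f_lo * tt) + sin(2 * pi * f_hi * tt),
                      rate = 0.5)
  expect_gt(lo, hi)
  expect_error(compute_falff(rnorm(100), rate = 0.3), "twice")
})
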