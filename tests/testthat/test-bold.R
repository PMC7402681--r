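# small synthetic trace pool: three g conditions, deterministic noise traces
mk_traces <- function(n_per = 2, len = 5000, rate = 1000) {
  out <- list()
  i <- 0
  for (g in c(5, 9, 12)) for (r in seq_len(n_per)) {
    i <- i + 1
    set.seed(400 + i)
    out[[i]] <- lfp_trace(abs(rnorm(len)) + 1, rate, meta = list(g = g, nu0 = 1.5))
  }
  out
}

test_that("aggregation groups by g and concatenates to the requested length", {
  traces <- mk_traces()
  aggs <- aggregate_lfp(traces, n_concat = 20, n_reps = 2, seed = 3)
  expect_length(aggs, 6)
  expect_true(all(sapply(aggs, function(a) a$duration) == 20 * traces[[1]]$duration))
  grp <- sapply(aggs, function(a) a$g_group)
  expect_equal(sort(unique(grp)), c("high", "low", "mid"))
  # g = 5 traces land in the low group only
  low_src <- unlist(lapply(aggs[grp == "low"], function(a) a$source_ids))
  expect_true(all(low_src %in% 1:2))
  # n_concat = 1 reproduces a single source trace
  one <- aggregate_lfp(traces, n_concat = 1, n_reps = 1, seed = 9)
  a1 <- one[[1]]
  expect_equal(a1$samples, traces[[a1$source_ids]]$samples)
  # an empty group is an error naming the bounds
  expect_error(aggregate_lfp(traces[1:2], n_reps = 1), "bounds|group")
  # deterministic under the seed
  b <- aggregate_lfp(traces, n_concat = 20, n_reps = 2, seed = 3)
  expect_identical(sapply(b, function(a) a$source_ids),
                   sapply(aggs, function(a) a$source_ids))
})

test_that("low-frequency extrapolation is a fixed point on exact power laws", {
  # build a signal with an exact power-law amplitude spectrum, slope -1.5
  n <- 60000; rate <- 1000
  freqs <- seq(0, n - 1) * rate / n
  half <- 2:(n / 2)
  amp <- numeric(n)
  amp[half] <- freqs[half]^(-1.5 / 2)
  set.seed(5)
  ph <- runif(length(half), 0, 2 * pi)
  X <- complex(modulus = 0, argument = 0) * numeric(n)
  X[half] <- amp[half] * exp(1i * ph)
  X[n + 2 - half] <- Conj(X[half])
  x <- Re(fft(X, inverse = TRUE)) / n
  tr <- lfp_trace(x, rate, meta = list(g = 9))

  ex <- extrapolate_low_freq(tr, slope_low = -1.5, f_below = 1, seed = 11)
  P0 <- abs(fft(tr$samples))^2
  P1 <- abs(fft(ex$samples))^2
  low <- which(freqs > 0 & freqs < 1)
  # amplitudes below 1 Hz stay on the same power law within 5%
  expect_lt(max(abs(P1[low] / P0[low] - 1)), 0.05)

  # slope 0 request gives a flat deterministic amplitude profile below f_below
  ex0 <- extrapolate_low_freq(tr, slope_low = 0, f_below = 1, seed = 12)
  A0 <- abs(fft(ex0$samples))[low]
  expect_lt(diff(range(A0)) / mean(A0), 0.01)

  # round trip: refitting the extrapolated region recovers the requested slope
  ex2 <- extrapolate_low_freq(tr, slope_low = -2.5, f_below = 1, seed = 13)
  A2 <- abs(fft(ex2$samples))[low]
  fit <- cov(log10(freqs[low]), log10(A2^2)) / var(log10(freqs[low]))
  expect_lt(abs(fit - (-2.5)), 0.1)
  expect_error(extrapolate_low_freq(tr, -1, f_below = 600), "Nyquist")
})

test_that("the high-pass filter meets its printed calibration", {
  hpf <- design_hpf()
  fs <- seq(0.01, 100, by = 0.01)
  gain <- hpf_gain(hpf, fs)
  peak <- max(gain)
  expect_lt(abs(fs[which.max(gain)] - 20), 0.011)
  expect_lt(abs(hpf_gain(hpf, 12.5) / peak - 1 / sqrt(2)), 0.02 / sqrt(2))
  expect_lt(hpf_gain(hpf, 1e-9) , 0.01 * peak)
  expect_error(design_hpf(25, 20), "f_3dB")
})

test_that("HRF kernels peak where documented and decay", {
  can <- make_hrf("canonical", rate = 100)
  expect_lt(abs((which.max(can$kernel) - 1) / 100 - 6), 0.011)
  expect_equal(max(can$kernel), 1)
  # biphasic tail is effectively zero by the end of the 32 s support
  expect_lt(max(abs(can$kernel[3101:3201])), 2.1e-3)
  expect_lt(abs(can$kernel[3201]), 1e-3)
  gb <- make_hrf("gamma_band_derived", rate = 100)
  expect_lt(abs((which.max(gb$kernel) - 1) / 100 - gb$params$peak_s), 0.5)
  expect_lt(max(abs(gb$kernel[3101:3201])), 1e-3)
  # transform identity: spectrum at 0 Hz equals kernel sum / rate
  sp <- eihurst:::hrf_spectrum(gb, 8192)
  expect_equal(Re(sp[1]), sum(gb$kernel) / gb$rate, tolerance = 1e-9)
  expect_error(make_hrf("boxcar", rate = 100), "arg")
})

test_that("the forward model is linear, counts samples, and filters", {
  hpf <- design_hpf()
  hrf <- make_hrf("gamma_band_derived", rate = 1000)
  set.seed(21)
  x <- abs(rnorm(200000)) + 1
  tr <- lfp_trace(x, 1000, meta = list(g = 9))
  b1 <- lfp_to_bold(tr, hpf, hrf, eta_amplitude = 0, out_rate = 0.5)
  expect_length(b1$samples, 100)  # 200 s at 0.5 Hz
  # linearity with eta = 0
  tr3 <- lfp_trace(3 * x, 1000, meta = list(g = 9))
  b3 <- lfp_to_bold(tr3, hpf, hrf, eta_amplitude = 0, out_rate = 0.5)
  expect_equal(b3$samples, 3 * b1$samples, tolerance = 1e-9)
  expect_error(lfp_to_bold(tr, hpf, hrf, eta_amplitude = -1), "non-negative")

  # white-noise input: output spectrum proportional to |HPF x HRF|^2 below
  # the anti-alias edge (averaged over seeds)
  n <- 200000
  freqs <- seq(0, n - 1) / n * 1000
  keep <- freqs > 0.005 & freqs < 0.16
  gain2 <- (hpf_gain(hpf, freqs) * abs(eihurst:::hrf_spectrum(hrf, n)))^2
  acc <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    w <- rnorm(n)
    bw <- lfp_to_bold(lfp_trace(w + 10, 1000), hpf, hrf, eta_amplitude = 0,
                      out_rate = 0.5)
    # compare in the full-rate frequency domain before decimation artefacts:
    # recompute from the model identity instead using the output periodogram
    acc <- acc + abs(fft(bw$samples))^2
  }
  out_freqs <- seq(0, 99) / 100 * 0.5
  sel_out <- out_freqs > 0.005 & out_freqs < 0.16
  ratio <- (acc[sel_out] / 20) /
    approx(freqs[keep], gain2[keep], xout = out_freqs[sel_out])$y
  ratio <- ratio / mean(ratio)
  # band-averaged flatness of the ratio within 35% (20-seed average)
  thirds <- cut(seq_along(ratio), 3)
  bandmeans <- tapply(ratio, thirds, mean)
  expect_lt(diff(range(bandmeans)) / mean(bandmeans), 0.35)
})

test_that("the full pipeline produces grouped BOLD series with provenance", {
  traces <- mk_traces()
  pp <- bold_pipeline(traces, n_reps = 2, seed = 7)
  expect_length(pp$bold, 6)
  expect_true(all(sapply(pp$bold, function(b) length(b$samples)) == 50))
  expect_setequal(unique(sapply(pp$bold, function(b) b$meta$g_group)),
                  c("low", "mid", "high"))
})
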