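#' Construct a BOLD series object
#'
#' @param samples Numeric vector.
#' @param rate Sampling rate, Hz (0.5 Hz in typical BOLD experiments).
#' @param meta Named list of provenance (g group, eta, hrf kind, seed, ...).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(samples, rate = 0.5, meta = list()) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate,
                 duration = length(samples) / rate, meta = meta),
            class = "bold_series")
}

#' Group and concatenate LFP traces
#'
#' Traces are assigned to three g groups (low: g below `bounds[1]`, mid:
#' between the bounds, high: above `bounds[2]`). Per group and repetition,
#' `n_concat` member traces are drawn with replacement in random order and
#' concatenated end-to-end, turning 10-s traces into 200-s signals with the
#' defaults.
#'
#' @param traces List of `lfp_trace` objects of equal duration and rate,
#'   each carrying its g in `meta$g`.
#' @param bounds Group boundaries `c(low_upper, mid_upper)` on g.
#' @param n_concat Traces concatenated per aggregate.
#' @param n_reps Repetitions (random orderings) per group.
#' @param seed Integer seed for the orderings.
#' @return A list of `aggregated_lfp` objects (also of class `lfp_trace`),
#'   each with `g_group`, `repetition` and `source_ids`.
#' @export
aggregate_lfp <- function(traces, bounds = c(7.5, 11), n_concat = 20,
                          n_reps = 20, seed = 1L) {
  stopifnot(length(traces) > 0)
  rates <- vapply(traces, function(tr) tr$rate, 0)
  durs <- vapply(traces, function(tr) tr$duration, 0)
  if (length(unique(rates)) != 1 || diff(range(durs)) > 1e-9) {
    stop("all traces must share one duration and rate")
  }
  g <- vapply(traces, function(tr) tr$meta$g, 0)
  group <- ifelse(g < bounds[1], "low", ifelse(g > bounds[2], "high", "mid"))
  set.seed(seed)
  out <- list()
  for (grp in c("low", "mid", "high")) {
    members <- which(group == grp)
    if (length(members) == 0) {
      stop(sprintf("no traces in g group '%s' (bounds %g, %g)",
                   grp, bounds[1], bounds[2]))
    }
    for (rep_i in seq_len(n_reps)) {
      ids <- sample(members, n_concat, replace = TRUE)
      samples <- unlist(lapply(traces[ids], function(tr) tr$samples),
                        use.names = FALSE)
      agg <- lfp_trace(samples, rates[1],
                       meta = list(g = mean(g[ids]), nu0 = traces[[1]]$meta$nu0,
                                   condition = paste0("g_", grp), seed = seed))
      agg$g_group <- grp
      agg$repetition <- rep_i
      agg$source_ids <- ids
      class(agg) <- c("aggregated_lfp", class(agg))
      out[[length(out) + 1]] <- agg
    }
  }
  out
}

#' Replace low frequencies by a power-law continuation
#'
#' Spectral amplitudes below `f_below` are replaced by the log-log linear
#' continuation of the fitted low-frequency slope, anchored at the signal's
#' own spectral level just above `f_below` (geometric mean over
#' `[f_below, 1.5 f_below]`). Phases below `f_below` are drawn uniformly
#' with Hermitian symmetry and the DC component is set to zero before the
#' inverse transform.
#'
#' @param agg An `lfp_trace` (typically an `aggregated_lfp`).
#' @param slope_low Log10-power per log10-Hz slope to continue.
#' @param f_below Boundary frequency, Hz.
#' @param seed Optional seed for the phase draw.
#' @return A trace of the same class with modified samples and
#'   `meta$extrapolated = TRUE`.
#' @export
extrapolate_low_freq <- function(agg, slope_low, f_below = 1, seed = NULL) {
  if (!is.finite(slope_low)) stop("slope_low must be finite")
  n <- length(agg$samples)
  rate <- agg$rate
  if (f_below >= rate / 2) stop("f_below must lie below the Nyquist frequency")
  if (!is.null(seed)) set.seed(seed)
  X <- fft(agg$samples)
  freqs <- seq(0, n - 1) * rate / n
  half <- 2:(ceiling(n / 2))  # positive-frequency bins excluding DC
  f_half <- freqs[half]
  anchor_sel <- f_half >= f_below & f_half <= 1.5 * f_below
  if (!any(anchor_sel)) stop("no spectral bins available to anchor at f_below")
  a_anchor <- exp(mean(log(pmax(abs(X[half][anchor_sel]), 1e-300))))
  f_anchor <- exp(mean(log(f_half[anchor_sel])))
  low <- which(f_half < f_below)
  if (length(low) > 0) {
    amp <- a_anchor * (f_half[low] / f_anchor)^(slope_low / 2)
    phase <- runif(length(low), 0, 2 * pi)
    X[half[low]] <- amp * exp(1i * phase)
    X[n + 2 - half[low]] <- Conj(X[half[low]])
  }
  X[1] <- 0
  out <- agg
  out$samples <- Re(fft(X, inverse = TRUE)) / n
  out$meta$extrapolated <- TRUE
  out$meta$slope_low <- slope_low
  out
}

#' Design the resonant high-pass filter of the BOLD forward model
#'
#' A second-order resonant high-pass magnitude response
#' `|H(f)|^2 = f^4 / ((f0^2 - f^2)^2 + (f0 f / Q)^2)` whose natural
#' frequency and damping are solved numerically so that the response peaks
#' at `f_peak` and is 3 dB below the peak at `f_3dB` (the cutoff convention
#' is relative to the peak response).
#'
#' @param f_3dB Frequency where the response is 3 dB below peak, Hz.
#' @param f_peak Frequency of maximal response, Hz.
#' @return An object of class `hpf_spec` with the solved `f0` and `Q`, the
#'   calibration targets, and a sampled magnitude response.
#' @export
design_hpf <- function(f_3dB = 12.5, f_peak = 20) {
  if (!(f_3dB > 0 && f_3dB < f_peak)) stop("need 0 < f_3dB < f_peak")
  mag2 <- function(f, f0, q) {
    f^4 / ((f0^2 - f^2)^2 + (f0 * f / q)^2)
  }
  # peak of a 2nd-order high-pass: f_peak = f0 / sqrt(1 - 1/(2 Q^2)), Q > 1/sqrt(2)
  resid <- function(q) {
    f0 <- f_peak * sqrt(1 - 1 / (2 * q^2))
    2 * mag2(f_3dB, f0, q) - mag2(f_peak, f0, q)
  }
  lo <- 1 / sqrt(2) + 1e-6
  hi <- 200
  if (resid(lo) * resid(hi) > 0) {
    stop("no second-order resonant high-pass satisfies this (f_3dB, f_peak) pair")
  }
  q <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  f0 <- f_peak * sqrt(1 - 1 / (2 * q^2))
  f_grid <- seq(0, 4 * f_peak, length.out = 2048)
  structure(list(f0 = f0, Q = q, f_3dB = f_3dB, f_peak = f_peak,
                 response = data.frame(freq = f_grid,
                                       gain = sqrt(mag2(f_grid, f0, q)))),
            class = "hpf_spec")
}

#' Amplitude gain of an `hpf_spec` at arbitrary frequencies
#'
#' @param hpf An `hpf_spec`.
#' @param f Frequencies, Hz.
#' @return Non-negative amplitude gains.
#' @export
hpf_gain <- function(hpf, f) {
  stopifnot(inherits(hpf, "hpf_spec"))
  sqrt(f^4 / ((hpf$f0^2 - f^2)^2 + (hpf$f0 * f / hpf$Q)^2))
}

#' Hemodynamic response function kernel
#'
#' Two kinds are provided. `"canonical"` is the biphasic double-gamma
#' (response peak at 6 s, undershoot peak at 16 s, undershoot ratio 1/6).
#' `"gamma_band_derived"` stands in for the empirically derived kernel that
#' reproduces the measured correlation between gamma-band field-potential
#' power and BOLD: it is likewise biphasic (response peak `peak_s`, default
#' 4 s, with an undershoot at `undershoot_s` weighted by
#' `undershoot_ratio`). Kernels are normalized to unit peak.
#'
#' @param kind `"gamma_band_derived"` or `"canonical"`.
#' @param rate Sampling rate of the kernel, Hz.
#' @param duration_s Kernel support, s.
#' @param peak_s,undershoot_s,undershoot_ratio Shape parameters of the
#'   gamma-band-derived kernel.
#' @return An object of class `hrf_kernel` with the sampled `kernel`, its
#'   `rate`, `kind` and parameter list.
#' @export
make_hrf <- function(kind = c("gamma_band_derived", "canonical"), rate,
                     duration_s = 32, peak_s = 4, undershoot_s = 10,
                     undershoot_ratio = 0.5) {
  kind <- match.arg(kind)
  if (rate <= 0) stop("rate must be positive")
  t <- seq(0, duration_s, by = 1 / rate)
  if (kind == "canonical") {
    # gamma(shape, rate = 1) has mode shape - 1: peaks at 6 s and 16 s
    k <- stats::dgamma(t, shape = 7, rate = 1) -
      stats::dgamma(t, shape = 17, rate = 1) / 6
    params <- list(peak_s = 6, undershoot_s = 16, undershoot_ratio = 1 / 6)
  } else {
    shape1 <- 5
    theta1 <- peak_s / (shape1 - 1)
    shape2 <- 9
    theta2 <- undershoot_s / (shape2 - 1)
    main <- stats::dgamma(t, shape = shape1, scale = theta1)
    under <- stats::dgamma(t, shape = shape2, scale = theta2)
    k <- main / max(main) - undershoot_ratio * under / max(under)
    params <- list(peak_s = peak_s, undershoot_s = undershoot_s,
                   undershoot_ratio = undershoot_ratio,
                   shape = c(shape1, shape2))
  }
  k <- k / max(k)
  structure(list(kind = kind, params = params, kernel = k, rate = rate,
                 duration_s = duration_s),
            class = "hrf_kernel")
}

#' Spectrum of an HRF kernel at given frequencies (via zero-padded FFT)
#' @param hrf An `hrf_kernel`.
#' @param n Transform length in samples at the kernel rate.
#' @return Complex spectrum of length `n` (fft bin order).
#' @keywords internal
hrf_spectrum <- function(hrf, n) {
  k <- hrf$kernel
  if (length(k) > n) stop("transform shorter than the HRF kernel")
  fft(c(k, rep(0, n - length(k)))) / hrf$rate
}

#' Forward-model BOLD from an LFP trace
#'
#' Multiplies the LFP spectrum by the amplitude response of the high-pass
#' filter and the complex spectrum of the HRF, adds a small complex white
#' noise term (Hermitian-symmetric, representing neurovascular variability
#' at frequencies faster than the BOLD acquisition), inverse-transforms,
#' removes content above 80% of the output Nyquist frequency
#' (spectral-domain anti-alias) and decimates to `out_rate`.
#'
#' @param lfp An `lfp_trace` / `aggregated_lfp`.
#' @param hpf An `hpf_spec`.
#' @param hrf An `hrf_kernel` sampled at the LFP rate.
#' @param eta_amplitude Amplitude of the white spectral noise term; `NULL`
#'   uses 1e-4 times the median LFP spectral amplitude. Must be >= 0.
#' @param out_rate Output sampling rate, Hz; the LFP rate must be an
#'   integer multiple.
#' @param seed Optional seed for the noise term.
#' @return A [bold_series()].
#' @export
lfp_to_bold <- function(lfp, hpf, hrf, eta_amplitude = NULL, out_rate = 0.5,
                        seed = NULL) {
  stopifnot(inherits(hpf, "hpf_spec"), inherits(hrf, "hrf_kernel"))
  if (!is.null(eta_amplitude) && eta_amplitude < 0) {
    stop("eta_amplitude must be non-negative")
  }
  rate <- lfp$rate
  if (rate <= 2 * out_rate) stop("LFP rate must greatly exceed out_rate")
  fac <- rate / out_rate
  if (abs(fac - round(fac)) > 1e-9) {
    stop("LFP rate must be an integer multiple of out_rate")
  }
  fac <- round(fac)
  if (!is.null(seed)) set.seed(seed)
  n <- length(lfp$samples)
  X <- fft(lfp$samples)
  freqs <- seq(0, n - 1) * rate / n
  freqs_sym <- pmin(freqs, rate - freqs)  # two-sided frequency magnitude
  if (is.null(eta_amplitude)) {
    eta_amplitude <- 1e-4 * stats::median(abs(X[-1]))
  }
  Y <- X * hpf_gain(hpf, freqs_sym) * hrf_spectrum(hrf, n)
  if (eta_amplitude > 0) {
    half <- 2:(ceiling(n / 2))
    z <- eta_amplitude * (rnorm(length(half)) + 1i * rnorm(length(half))) /
      sqrt(2)
    Y[half] <- Y[half] + z
    Y[n + 2 - half] <- Conj(Y[half])
  }
  Y[freqs_sym > 0.8 * out_rate / 2] <- 0
  y <- Re(fft(Y, inverse = TRUE)) / n
  samples <- y[seq(1, n, by = fac)]
  bold_series(samples, out_rate,
              meta = c(lfp$meta[intersect(names(lfp$meta),
                                          c("g", "nu0", "condition"))],
                       list(eta = eta_amplitude, hrf = hrf$kind, seed = seed,
                            source_duration = lfp$duration)))
}

#' Run the full LFP-to-BOLD forward pipeline on a set of traces
#'
#' Fits the low-frequency 1/f slope of each source trace, aggregates traces
#' into per-group concatenations, extrapolates their low-frequency content
#' with the mean source slope, and forward-models each aggregate into a
#' BOLD series.
#'
#' @param traces List of `lfp_trace` objects with `meta$g` set.
#' @param bounds,n_concat,n_reps As in [aggregate_lfp()].
#' @param hrf_kind Kernel passed to [make_hrf()].
#' @param eta_amplitude,out_rate As in [lfp_to_bold()].
#' @param f_below Extrapolation boundary, Hz.
#' @param seed Integer seed.
#' @return List with `bold` (list of `bold_series`), `aggregates`, `hpf`,
#'   `hrf` and the per-trace `slopes`.
#' @export
bold_pipeline <- function(traces, bounds = c(7.5, 11), n_concat = 20,
                          n_reps = 20, hrf_kind = "gamma_band_derived",
                          eta_amplitude = NULL, out_rate = 0.5, f_below = 1,
                          seed = 1L) {
  slopes <- vapply(traces, function(tr) {
    fit_piecewise_slopes(welch_psd(tr$samples, tr$rate))$slope_low
  }, 0)
  aggs <- aggregate_lfp(traces, bounds, n_concat, n_reps, seed)
  hpf <- design_hpf()
  hrf <- make_hrf(hrf_kind, rate = traces[[1]]$rate)
  bold <- vector("list", length(aggs))
  for (i in seq_along(aggs)) {
    sl <- mean(slopes[aggs[[i]]$source_ids])
    ex <- extrapolate_low_freq(aggs[[i]], sl, f_below = f_below,
                               seed = seed + i)
    bold[[i]] <- lfp_to_bold(ex, hpf, hrf, eta_amplitude = eta_amplitude,
                             out_rate = out_rate, seed = seed + 10000 + i)
    bold[[i]]$meta$g_group <- aggs[[i]]$g_group
    bold[[i]]$meta$repetition <- aggs[[i]]$repetition
  }
  list(bold = bold, aggregates = aggs, hpf = hpf, hrf = hrf, slopes = slopes)
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %.3g s at %g Hz (%d samples)\n",
              x$duration, x$rate, length(x$samples)))
  invisible(x)
}

#' @export
print.hpf_spec <- function(x, ...) {
  cat(sprintf("<hpf_spec> f0 = %.3f Hz, Q = %.3f (peak %.3g Hz, -3 dB %.3g Hz)\n",
              x$f0, x$Q, x$f_peak, x$f_3dB))
  invisible(x)
}
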