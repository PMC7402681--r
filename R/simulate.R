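#' @useDynLib eihurst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois fft approx optim optimize sd cor
#'   var cov median quantile phyper pnorm prcomp uniroot dgamma nextn
NULL

# Build the flat parameter list consumed by the compiled integrator and draw
# the seed-controlled structural randomness (connectivity, initial voltages,
# OU rate trace) in a fixed order. Everything the integrator consumes besides
# the per-bin Poisson counts is produced here so that a reference integrator
# can be run on the identical realization.
lif_prepare <- function(config) {
  stopifnot(inherits(config, "network_config"))
  n <- config$n_e + config$n_i
  n_samples <- round(config$duration * config$lfp_rate)
  steps_per_bin <- 1000 / (config$lfp_rate * config$dt)
  if (abs(steps_per_bin - round(steps_per_bin)) > 1e-9) {
    stop("1 / lfp_rate must be an integer multiple of dt")
  }
  set.seed(config$seed)

  # Bernoulli connectivity per ordered pair, no autapses; adjacency stored as
  # a concatenated 0-based target vector with per-neuron offsets
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- which(runif(n) < config$p_conn)
    tg <- tg[tg != i]
    targets[[i]] <- tg - 1L
  }
  offsets <- c(0L, cumsum(lengths(targets)))
  conn_targets <- as.integer(unlist(targets, use.names = FALSE))

  # start near rest: a small spread decorrelates neurons without seeding an
  # onset volley (the external drive is ramped in over ramp_s as well)
  v_init <- runif(n, config$pop_e$v_leak, config$pop_e$v_leak + 5)

  # zero-mean OU rate trace at the input-bin resolution (exact discretization)
  bin_ms <- 1000 / config$lfp_rate
  rho <- exp(-bin_ms / config$ou_tau)
  ou <- numeric(max(n_samples, 1))
  ou[1] <- rnorm(1, 0, config$ou_sigma)
  if (n_samples > 1) {
    innov <- rnorm(n_samples - 1, 0, config$ou_sigma * sqrt(1 - rho^2))
    for (b in 2:n_samples) ou[b] <- rho * ou[b - 1] + innov[b - 1]
  }

  cfg_list <- list(
    n_e = config$n_e, n_i = config$n_i,
    dt = config$dt, duration = config$duration, lfp_rate = config$lfp_rate,
    nu0 = config$nu0, n_ext = config$n_ext, ramp_s = config$ramp_s,
    ou_independent = identical(config$ou_mode, "independent"),
    ou_rho = exp(-1000 / (config$lfp_rate * config$ou_tau)),
    ou_innov_sd = config$ou_sigma *
      sqrt(1 - exp(-2000 / (config$lfp_rate * config$ou_tau))),
    v_leak = c(config$pop_e$v_leak, config$pop_i$v_leak),
    v_threshold = c(config$pop_e$v_threshold, config$pop_i$v_threshold),
    v_reset = c(config$pop_e$v_reset, config$pop_i$v_reset),
    tau_refractory = c(config$pop_e$tau_refractory, config$pop_i$tau_refractory),
    g_leak = c(config$pop_e$g_leak, config$pop_i$g_leak),
    c_m = c(config$pop_e$c_m, config$pop_i$c_m),
    tau_r_ampa = config$syn$tau_r_ampa, tau_d_ampa = config$syn$tau_d_ampa,
    tau_r_gaba = config$syn$tau_r_gaba, tau_d_gaba = config$syn$tau_d_gaba,
    g_ampa_rec = config$syn$g_ampa_rec, g_ampa_tha = config$syn$g_ampa_tha,
    g_ampa_cort = config$syn$g_ampa_cort, g_gaba = config$syn$g_gaba,
    e_ampa = config$syn$e_ampa, e_gaba = config$syn$e_gaba,
    latency = config$syn$latency
  )
  list(cfg = cfg_list, conn_targets = conn_targets, conn_offsets = offsets,
       ou = ou, v_init = v_init, n_samples = n_samples)
}

#' Simulate the recurrent E/I network
#'
#' Integrates the conductance-based LIF dynamics (exponential decay of the
#' difference-of-exponentials synaptic gating, forward-Euler membrane update,
#' absolute refractory clamp at the reset potential while conductances keep
#' evolving) and records the total AMPA and GABA synaptic currents summed
#' over excitatory cells at `lfp_rate`. The thalamic drive is homogeneous
#' Poisson at `nu0` per external synapse; the intracortical drive is a
#' Poisson process whose rate follows a zero-mean Ornstein-Uhlenbeck process
#' rectified at zero. Identical configuration and seed give bit-identical
#' output.
#'
#' @param config A [network_config()].
#' @return An object of class `sim_output`: a list with `spikes` (data frame
#'   of 1-based `neuron` id and `time` in s), `i_ampa` and `i_gaba` (summed
#'   currents over excitatory cells, nA, sampled at `lfp_rate`), `rates`
#'   (mean firing rate per population, spikes/s), `duration`, `lfp_rate`,
#'   and the originating `config`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  if (config$duration == 0) {
    return(structure(list(
      spikes = data.frame(neuron = integer(0), time = numeric(0)),
      i_ampa = numeric(0), i_gaba = numeric(0),
      rates = c(E = 0, I = 0), duration = 0,
      lfp_rate = config$lfp_rate, config = config
    ), class = "sim_output"))
  }
  prep <- lif_prepare(config)
  if (prep$n_samples < 1) {
    stop("duration must cover at least one LFP sample")
  }
  res <- lif_simulate_cpp(prep$cfg, prep$conn_targets, prep$conn_offsets,
                          prep$ou, prep$v_init)
  structure(list(
    spikes = data.frame(neuron = res$neuron, time = res$time),
    i_ampa = res$i_ampa, i_gaba = res$i_gaba,
    rates = c(E = res$rate_e, I = res$rate_i),
    duration = config$duration, lfp_rate = config$lfp_rate,
    config = config
  ), class = "sim_output")
}

#' LFP proxy from simulated synaptic currents
#'
#' The local field potential proxy is the sum of absolute values of the AMPA
#' and GABA postsynaptic currents on excitatory cells (external plus
#' recurrent sources), which makes the trace non-negative by construction.
#'
#' @param sim A `sim_output`.
#' @param rate Output sampling rate, Hz. Must equal the recorded current
#'   sampling rate or an integer divisor of it (in which case the trace is
#'   decimated by taking every k-th sample).
#' @return An object of class `lfp_trace` with fields `samples`, `rate`,
#'   `duration` and `meta` (g, nu0, condition, seed).
#' @export
compute_lfp <- function(sim, rate = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  if (is.null(sim$i_ampa) || is.null(sim$i_gaba)) {
    stop("simulation output carries no current traces")
  }
  if (is.null(rate)) rate <- sim$lfp_rate
  samples <- abs(sim$i_ampa) + abs(sim$i_gaba)
  if (rate != sim$lfp_rate) {
    k <- sim$lfp_rate / rate
    if (abs(k - round(k)) > 1e-9 || k < 1) {
      stop("rate must equal the recorded rate or divide it")
    }
    samples <- samples[seq(round(k), length(samples), by = round(k))]
  }
  lfp_trace(samples, rate,
            meta = list(g = ei_ratio(sim$config), nu0 = sim$config$nu0,
                        condition = "baseline", seed = sim$config$seed))
}

#' Construct an LFP trace object
#'
#' @param samples Numeric vector of field-potential samples.
#' @param rate Sampling rate, Hz.
#' @param meta Named list of provenance (g, nu0, condition, seed).
#' @return An object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, rate, meta = list()) {
  stopifnot(is.numeric(samples), rate > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), rate = rate,
                 duration = length(samples) / rate, meta = meta),
            class = "lfp_trace")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %d E + %d I neurons, %.3g s, %d spikes (E %.2f Hz, I %.2f Hz)\n",
    x$config$n_e, x$config$n_i, x$duration, nrow(x$spikes),
    x$rates["E"], x$rates["I"]))
  invisible(x)
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %.3g s at %g Hz (g = %.3g, nu0 = %.3g)\n",
              x$duration, x$rate,
              if (is.null(x$meta$g)) NA_real_ else x$meta$g,
              if (is.null(x$meta$nu0)) NA_real_ else x$meta$nu0))
  invisible(x)
}
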