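#' Specification of an in-silico sweep
#'
#' @param g_grid Values of the inhibition/excitation conductance ratio g to
#'   simulate; default 12 log-spaced values spanning 4-16 around the
#'   reference 11.3.
#' @param nu0 Thalamic input rates, spikes/s per external synapse.
#' @param n_reps Independent repetitions (seeds) per condition.
#' @param base Base [network_config()]; defaults to the reduced 500-neuron
#'   preset with 10 s per condition.
#' @param seeds Integer seeds, one per repetition.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(g_grid = exp(seq(log(4), log(16), length.out = 12)),
                       nu0 = c(1.5, 2), n_reps = 5,
                       base = reduced_preset(), seeds = seq_len(n_reps)) {
  if (length(g_grid) == 0) stop("g grid must be non-empty")
  if (any(nu0 <= 0)) stop("nu0 must be positive")
  stopifnot(length(seeds) == n_reps)
  structure(list(g_grid = g_grid, nu0 = nu0, n_reps = n_reps, base = base,
                 seeds = as.integer(seeds)),
            class = "sweep_spec")
}

# Run one condition: simulate, LFP, PSD, slopes, Hurst. Returns a one-row
# data frame; simulation failures are flagged rather than fatal.
run_condition <- function(config, label_cols) {
  row <- c(label_cols, list(
    seed = config$seed, rate_e = NA_real_, rate_i = NA_real_,
    slope_low = NA_real_, slope_high = NA_real_, h_lfp = NA_real_,
    ok = FALSE))
  res <- tryCatch({
    sim <- simulate_network(config)
    lfp <- compute_lfp(sim)
    psd <- welch_psd(lfp$samples, lfp$rate)
    sl <- fit_piecewise_slopes(psd)
    h <- estimate_hurst_fip(lfp$samples)
    list(sim = sim, sl = sl, h = h)
  }, error = function(e) e)
  if (!inherits(res, "error")) {
    row$rate_e <- unname(res$sim$rates["E"])
    row$rate_i <- unname(res$sim$rates["I"])
    row$slope_low <- res$sl$slope_low
    row$slope_high <- res$sl$slope_high
    row$h_lfp <- res$h$H
    row$ok <- TRUE
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Sweep the E:I conductance ratio
#'
#' For each (g, nu0, repetition) cell the base network is reconfigured to
#' the requested g, simulated, and summarized by its firing rates, the low-
#' and high-frequency 1/f slopes of the LFP power spectrum and the Hurst
#' exponent of the LFP. Seeds are recorded per row, so reruns with the same
#' spec reproduce the table exactly.
#'
#' @param spec A [sweep_spec()].
#' @param keep_traces If `TRUE`, the LFP traces are returned alongside the
#'   table (needed to forward-model BOLD afterwards).
#' @return A data frame (class `sweep_result`) with one row per condition
#'   and repetition; with `keep_traces`, a list of `lfp_trace` objects is
#'   attached as attribute `traces` (row-aligned).
#' @export
run_g_sweep <- function(spec, keep_traces = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  traces <- list()
  idx <- 0L
  for (g in spec$g_grid) {
    for (nu in spec$nu0) {
      for (r in seq_len(spec$n_reps)) {
        idx <- idx + 1L
        cfg <- configure_ei_ratio(spec$base, g)
        cfg$nu0 <- nu
        cfg$ou_sigma <- 0.4 * nu
        cfg$seed <- spec$seeds[r] + 7919L * idx
        rows[[idx]] <- run_condition(cfg, list(g = g, nu0 = nu, rep = r))
        if (keep_traces && rows[[idx]]$ok) {
          traces[[idx]] <- compute_lfp(simulate_network(cfg))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' Sweep a chemogenetic-style parameter manipulation
#'
#' Applies either the excitatory-threshold manipulation (`"excite_vth"`,
#' lowering the excitatory spike threshold to mimic enhanced excitability of
#' pyramidal cells) or the pan-neuronal silencing manipulation
#' (`"silence_el"`, lowering the leak potential of both populations) for
#' each requested value, and runs the same per-condition pipeline as
#' [run_g_sweep()].
#'
#' @param spec A [sweep_spec()] (its g grid is ignored; the base g is kept).
#' @param mode `"excite_vth"` or `"silence_el"`.
#' @param values Parameter values, mV (thresholds for `excite_vth`, leak
#'   potentials for `silence_el`).
#' @return A `sweep_result` data frame with a `value` column.
#' @export
run_dreadd_sweep <- function(spec, mode = c("excite_vth", "silence_el"),
                             values) {
  stopifnot(inherits(spec, "sweep_spec"))
  mode <- match.arg(mode)
  rows <- list()
  idx <- 0L
  for (v in values) {
    for (nu in spec$nu0) {
      for (r in seq_len(spec$n_reps)) {
        idx <- idx + 1L
        cfg <- if (mode == "excite_vth") {
          apply_excitatory_dreadd(spec$base, v)
        } else {
          apply_silencing_dreadd(spec$base, v)
        }
        cfg$nu0 <- nu
        cfg$ou_sigma <- 0.4 * nu
        cfg$seed <- spec$seeds[r] + 7919L * idx
        rows[[idx]] <- run_condition(cfg, list(mode = mode, value = v, nu0 = nu,
                                               rep = r))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Pool Hurst exponents into equal-size g groups
#'
#' Conditions are ranked by g and split into `n_groups` equal-size groups
#' (low to high); H samples are pooled per group. When the number of
#' distinct g values is not divisible by `n_groups`, a largest-remainder
#' assignment is used with a warning.
#'
#' @param result A `sweep_result` from [run_g_sweep()].
#' @param n_groups Number of groups.
#' @return An object of class `grouped_h`: a list with `group` labels,
#'   `members` (g values per group) and `h` (pooled H samples per group).
#' @export
group_h_by_g <- function(result, n_groups = 3) {
  gs <- sort(unique(result$g))
  if (length(gs) < n_groups) stop("need at least n_groups distinct g values")
  if (length(gs) %% n_groups != 0) {
    warning("distinct g count not divisible by n_groups; ",
            "using largest-remainder group sizes")
  }
  sizes <- rep(length(gs) %/% n_groups, n_groups)
  extra <- length(gs) %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- if (n_groups == 3) c("low", "medium", "high") else
    paste0("group", seq_len(n_groups))
  assign <- rep(labels, times = sizes)
  members <- split(gs, assign)[labels]
  h <- lapply(members, function(m) {
    result$h_lfp[result$g %in% m & result$ok]
  })
  structure(list(group = labels, members = members, h = h),
            class = "grouped_h")
}

#' Write a sweep result as tidy delimited text
#'
#' @param result A `sweep_result`.
#' @param path Output file path (tab-separated, with header).
#' @export
write_sweep_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
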