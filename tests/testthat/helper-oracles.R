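# Independent reference implementations used as test oracles. These are kept
# deliberately naive (straight transcription of the model equations) and
# separate from the package internals they check.

# Brute-force R integrator for the conductance LIF network at a finer time
# step. Reuses lif_prepare() for the structural randomness and reproduces the
# integrator's external-input draw order exactly (per input bin: one Poisson
# vector for the thalamic drive, then one for the rectified-OU intracortical
# drive when its rate is positive), so spike trains are comparable
# realization-by-realization.
oracle_simulate <- function(config, dt_divisor = 10) {
  prep <- eihurst:::lif_prepare(config)
  cfg <- prep$cfg
  n_e <- cfg$n_e
  n <- cfg$n_e + cfg$n_i
  dt <- cfg$dt / dt_divisor
  n_samples <- prep$n_samples
  steps_per_bin <- round(1000 / (cfg$lfp_rate * dt))
  n_steps <- n_samples * steps_per_bin
  bin_s <- 1 / cfg$lfp_rate

  pop <- c(rep(1L, cfg$n_e), rep(2L, cfg$n_i))
  peak_norm <- function(tr, td) {
    tp <- td * tr / (td - tr) * log(td / tr)
    1 / (exp(-tp / td) - exp(-tp / tr))
  }
  na <- peak_norm(cfg$tau_r_ampa, cfg$tau_d_ampa)
  ng <- peak_norm(cfg$tau_r_gaba, cfg$tau_d_gaba)
  dec_ad <- exp(-dt / cfg$tau_d_ampa)[pop]
  dec_ar <- exp(-dt / cfg$tau_r_ampa)[pop]
  dec_gd <- exp(-dt / cfg$tau_d_gaba)[pop]
  dec_gr <- exp(-dt / cfg$tau_r_gaba)[pop]
  w_tha <- (cfg$g_ampa_tha * na)[pop]
  w_cort <- (cfg$g_ampa_cort * na)[pop]
  w_rec <- (cfg$g_ampa_rec * na)
  w_gab <- (cfg$g_gaba * ng)
  v_leak <- cfg$v_leak[pop]; v_th <- cfg$v_threshold[pop]
  v_reset <- cfg$v_reset[pop]; g_leak <- cfg$g_leak[pop]; c_m <- cfg$c_m[pop]
  ref_steps <- round(cfg$tau_refractory / dt)[pop]

  adj <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- prep$conn_offsets[i] + 1
    hi <- prep$conn_offsets[i + 1]
    adj[[i]] <- if (hi >= lo) prep$conn_targets[lo:hi] + 1L else integer(0)
  }

  v <- prep$v_init
  xad <- xar <- xgd <- xgr <- numeric(n)
  pend_a <- pend_g <- numeric(n)
  refr <- integer(n)
  spk_id <- integer(0); spk_t <- numeric(0)

  for (s in seq_len(n_steps) - 1L) {
    if (s %% steps_per_bin == 0) {
      b <- s %/% steps_per_bin
      ramp <- if (cfg$ramp_s > 0) min(1, b * bin_s / cfg$ramp_s) else 1
      lam_t <- ramp * cfg$nu0 * cfg$n_ext * bin_s
      pend_a <- pend_a + w_tha * rpois(n, lam_t)
      lam_c <- ramp * max(0, prep$ou[b + 1]) * cfg$n_ext * bin_s
      if (lam_c > 0) pend_a <- pend_a + w_cort * rpois(n, lam_c)
    }
    xad <- xad * dec_ad + pend_a
    xar <- xar * dec_ar + pend_a
    xgd <- xgd * dec_gd + pend_g
    xgr <- xgr * dec_gr + pend_g
    pend_a[] <- 0; pend_g[] <- 0

    active <- refr == 0
    refr[!active] <- refr[!active] - 1L
    v[!active] <- v_reset[!active]
    ga <- xad - xar; gg <- xgd - xgr
    dv <- (-g_leak * (v - v_leak) - ga * (v - cfg$e_ampa) -
             gg * (v - cfg$e_gaba)) * dt / c_m
    v[active] <- v[active] + dv[active]
    fired <- which(active & v >= v_th)
    if (length(fired)) {
      spk_id <- c(spk_id, fired)
      spk_t <- c(spk_t, rep((s + 1) * dt / 1000, length(fired)))
      v[fired] <- v_reset[fired]
      refr[fired] <- ref_steps[fired]
      for (i in fired) {
        tg <- adj[[i]]
        if (length(tg) == 0) next
        if (i <= n_e) pend_a[tg] <- pend_a[tg] + w_rec[pop[tg]]
        else pend_g[tg] <- pend_g[tg] + w_gab[pop[tg]]
      }
    }
  }
  data.frame(neuron = spk_id, time = spk_t)
}

# Log2 wavelet-variance regression Hurst estimator (Abry-Veitch style):
# regress log2 of per-octave Haar detail variance on octave index; the slope
# is 2d, H = d + 1/2. Independent of the ML path it cross-checks.
oracle_hurst_logvar <- function(x, j_min = 2, j_max = NULL) {
  n <- length(x)
  if (is.null(j_max)) j_max <- floor(log2(n)) - 3
  lv <- j <- numeric(0)
  s <- x
  for (lev in seq_len(j_max)) {
    m <- floor(length(s) / 2)
    a <- s[2 * seq_len(m) - 1]; b <- s[2 * seq_len(m)]
    d <- (a - b) / sqrt(2)
    s <- (a + b) / sqrt(2)
    if (lev >= j_min) {
      lv <- c(lv, log2(mean(d^2)))
      j <- c(j, lev)
    }
  }
  slope <- cov(j, lv) / var(j)
  slope / 2 + 0.5
}

# Exhaustive hypergeometric upper tail by direct summation of the pmf
# (choose() products), independent of phyper().
oracle_hyper_tail <- function(overlap, n_a, n_b, background) {
  ks <- overlap:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(background - n_a, n_b - ks)) /
    choose(background, n_b)
}

# Frozen reduced-network configuration used across network-level tests.
test_preset <- function(seed, duration = 10, nu0 = 1.5, ...) {
  reduced_preset(duration = duration, nu0 = nu0, seed = seed, ...)
}
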