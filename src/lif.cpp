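#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Conductance-based LIF network integrator.
//
// Synaptic conductances are difference-of-exponentials normalized to unit
// peak; each channel is represented by a decaying pair (x_d, x_r) with
// g = x_d - x_r, both states decayed exactly (exponential Euler) and
// incremented at spike arrival by the peak-normalized weight. The membrane
// equation is advanced with forward Euler. Spikes propagate with a delay of
// one integration step. External input events are supplied as Poisson counts
// drawn inside the bin loop from R's RNG so that a reference integrator can
// reproduce the identical input realization.
//
// Units: mV, ms, nS, pF. Currents are returned in nA (nS * mV / 1000).

static double peak_norm(double tau_r, double tau_d) {
    double tp = tau_d * tau_r / (tau_d - tau_r) * std::log(tau_d / tau_r);
    return 1.0 / (std::exp(-tp / tau_d) - std::exp(-tp / tau_r));
}

// [[Rcpp::export]]
List lif_simulate_cpp(List cfg, IntegerVector conn_targets,
                      IntegerVector conn_offsets, NumericVector ou_rate,
                      NumericVector v_init) {
    const int n_e = cfg["n_e"], n_i = cfg["n_i"];
    const int n = n_e + n_i;
    const double dt = cfg["dt"];              // ms
    const double duration = cfg["duration"];  // s
    const double lfp_rate = cfg["lfp_rate"];  // Hz
    const int n_samples = (int)std::lround(duration * lfp_rate);
    const int steps_per_bin = (int)std::lround(1000.0 / (lfp_rate * dt));
    const int n_steps = n_samples * steps_per_bin;
    const double bin_s = 1.0 / lfp_rate;      // s per input bin
    const double nu0 = cfg["nu0"];
    const int n_ext = cfg["n_ext"];
    const double ramp_s = cfg["ramp_s"];
    const bool ou_indep = cfg["ou_independent"];
    const double ou_rho = cfg["ou_rho"];
    const double ou_innov_sd = cfg["ou_innov_sd"];

    // per-population parameters, index 0 = E, 1 = I
    NumericVector v_leak = cfg["v_leak"], v_th = cfg["v_threshold"],
                  v_reset = cfg["v_reset"], tau_ref = cfg["tau_refractory"],
                  g_leak = cfg["g_leak"], c_m = cfg["c_m"],
                  tau_r_a = cfg["tau_r_ampa"], tau_d_a = cfg["tau_d_ampa"],
                  tau_r_g = cfg["tau_r_gaba"], tau_d_g = cfg["tau_d_gaba"],
                  g_rec = cfg["g_ampa_rec"], g_tha = cfg["g_ampa_tha"],
                  g_cort = cfg["g_ampa_cort"], g_gab = cfg["g_gaba"];
    const double e_ampa = cfg["e_ampa"], e_gaba = cfg["e_gaba"];
    const double latency = cfg["latency"];   // ms
    const int delay_steps = std::max(1, (int)std::lround(latency / dt));

    double dec_ad[2], dec_ar[2], dec_gd[2], dec_gr[2], na[2], ng[2];
    double w_rec[2], w_tha[2], w_cort[2], w_gab[2];
    int ref_steps[2];
    for (int p = 0; p < 2; ++p) {
        dec_ad[p] = std::exp(-dt / tau_d_a[p]);
        dec_ar[p] = std::exp(-dt / tau_r_a[p]);
        dec_gd[p] = std::exp(-dt / tau_d_g[p]);
        dec_gr[p] = std::exp(-dt / tau_r_g[p]);
        na[p] = peak_norm(tau_r_a[p], tau_d_a[p]);
        ng[p] = peak_norm(tau_r_g[p], tau_d_g[p]);
        w_rec[p] = g_rec[p] * na[p];
        w_tha[p] = g_tha[p] * na[p];
        w_cort[p] = g_cort[p] * na[p];
        w_gab[p] = g_gab[p] * ng[p];
        ref_steps[p] = (int)std::lround(tau_ref[p] / dt);
    }

    std::vector<double> v(v_init.begin(), v_init.end());
    std::vector<double> xad(n, 0), xar(n, 0), xgd(n, 0), xgr(n, 0);
    // recurrent spikes are applied after the synaptic latency via a ring
    // buffer of pending conductance increments (external input is immediate)
    std::vector<double> pend_a(n, 0), pend_g(n, 0);
    std::vector<double> ring_a((size_t)delay_steps * n, 0.0);
    std::vector<double> ring_g((size_t)delay_steps * n, 0.0);
    std::vector<int> refr(n, 0);

    std::vector<double> ou_state;
    if (ou_indep) ou_state.assign(n, 0.0);
    std::vector<int> spike_id;
    std::vector<double> spike_t;
    NumericVector i_ampa(n_samples), i_gaba(n_samples);

    GetRNGstate();
    for (int s = 0; s < n_steps; ++s) {
        // external input at the first step of each bin: draw Poisson counts
        // (thalamic then intracortical, neuron order) from R's RNG
        if (s % steps_per_bin == 0) {
            int b = s / steps_per_bin;
            double ramp = (ramp_s > 0) ? std::min(1.0, b * bin_s / ramp_s) : 1.0;
            double lam_t = ramp * nu0 * n_ext * bin_s;
            for (int i = 0; i < n; ++i) {
                int p = (i < n_e) ? 0 : 1;
                double cnt = ::Rf_rpois(lam_t);
                pend_a[i] += w_tha[p] * cnt;
            }
            if (ou_indep) {
                // per-neuron OU rate: init draw at first bin, then AR(1);
                // draw order (all rnorm, then all rpois) matches the R oracle
                for (int i = 0; i < n; ++i) {
                    if (b == 0) ou_state[i] = ::Rf_rnorm(0.0, ou_innov_sd /
                                                         std::sqrt(1.0 - ou_rho * ou_rho));
                    else ou_state[i] = ou_rho * ou_state[i] +
                                       ::Rf_rnorm(0.0, ou_innov_sd);
                }
                for (int i = 0; i < n; ++i) {
                    int p = (i < n_e) ? 0 : 1;
                    double lam_i = ramp * std::max(0.0, ou_state[i]) * n_ext * bin_s;
                    if (lam_i > 0) pend_a[i] += w_cort[p] * ::Rf_rpois(lam_i);
                }
            } else {
                double lam_c = ramp * std::max(0.0, ou_rate[b]) * n_ext * bin_s;
                if (lam_c > 0) {
                    for (int i = 0; i < n; ++i) {
                        int p = (i < n_e) ? 0 : 1;
                        double cnt = ::Rf_rpois(lam_c);
                        pend_a[i] += w_cort[p] * cnt;
                    }
                }
            }
        }

        // pop the ring-buffer slot due at this step into the pending arrays
        {
            double *slot_a = &ring_a[(size_t)(s % delay_steps) * n];
            double *slot_g = &ring_g[(size_t)(s % delay_steps) * n];
            for (int i = 0; i < n; ++i) {
                pend_a[i] += slot_a[i];
                pend_g[i] += slot_g[i];
                slot_a[i] = 0.0;
                slot_g[i] = 0.0;
            }
        }

        // decay conductance states, add pending increments; flush values
        // below 1e-30 nS to zero (physically nil, avoids denormal stalls)
        for (int i = 0; i < n; ++i) {
            int p = (i < n_e) ? 0 : 1;
            xad[i] = xad[i] * dec_ad[p] + pend_a[i];
            xar[i] = xar[i] * dec_ar[p] + pend_a[i];
            xgd[i] = xgd[i] * dec_gd[p] + pend_g[i];
            xgr[i] = xgr[i] * dec_gr[p] + pend_g[i];
            if (xad[i] < 1e-30) xad[i] = 0.0;
            if (xar[i] < 1e-30) xar[i] = 0.0;
            if (xgd[i] < 1e-30) xgd[i] = 0.0;
            if (xgr[i] < 1e-30) xgr[i] = 0.0;
            pend_a[i] = 0.0;
            pend_g[i] = 0.0;
        }

        // membrane update (forward Euler), refractory clamp, threshold
        for (int i = 0; i < n; ++i) {
            int p = (i < n_e) ? 0 : 1;
            if (refr[i] > 0) {
                --refr[i];
                v[i] = v_reset[p];
                continue;
            }
            double ga = xad[i] - xar[i];
            double gg = xgd[i] - xgr[i];
            double dv = (-g_leak[p] * (v[i] - v_leak[p])
                         - ga * (v[i] - e_ampa)
                         - gg * (v[i] - e_gaba)) * dt / c_m[p];
            v[i] += dv;
            if (!std::isfinite(v[i])) {
                PutRNGstate();
                stop("membrane potential diverged (non-finite) at t = %f ms; "
                     "reduce the integration step dt = %f ms", s * dt, dt);
            }
            if (v[i] >= v_th[p]) {
                spike_id.push_back(i);
                spike_t.push_back((s + 1) * dt / 1000.0);
                v[i] = v_reset[p];
                refr[i] = ref_steps[p];
                bool is_e = i < n_e;
                double *slot_a = &ring_a[(size_t)(s % delay_steps) * n];
                double *slot_g = &ring_g[(size_t)(s % delay_steps) * n];
                for (int k = conn_offsets[i]; k < conn_offsets[i + 1]; ++k) {
                    int j = conn_targets[k];
                    int q = (j < n_e) ? 0 : 1;
                    if (is_e) slot_a[j] += w_rec[q];
                    else      slot_g[j] += w_gab[q];
                }
            }
        }

        // record summed synaptic currents on excitatory cells at bin ends
        if ((s + 1) % steps_per_bin == 0) {
            int b = (s + 1) / steps_per_bin - 1;
            double ia = 0, ig = 0;
            for (int i = 0; i < n_e; ++i) {
                ia += (xad[i] - xar[i]) * (v[i] - e_ampa);
                ig += (xgd[i] - xgr[i]) * (v[i] - e_gaba);
            }
            i_ampa[b] = ia / 1000.0;  // nS * mV -> nA
            i_gaba[b] = ig / 1000.0;
        }
    }
    PutRNGstate();

    int n_spk = spike_id.size();
    IntegerVector out_id(n_spk);
    NumericVector out_t(n_spk);
    double rate_e = 0, rate_i = 0;
    for (int k = 0; k < n_spk; ++k) {
        out_id[k] = spike_id[k] + 1;  // 1-based for R
        out_t[k] = spike_t[k];
        if (spike_id[k] < n_e) rate_e += 1.0; else rate_i += 1.0;
    }
    if (duration > 0) {
        rate_e /= n_e * duration;
        rate_i /= n_i * duration;
    }
    return List::create(_["neuron"] = out_id, _["time"] = out_t,
                        _["i_ampa"] = i_ampa, _["i_gaba"] = i_gaba,
                        _["rate_e"] = rate_e, _["rate_i"] = rate_i);
}
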