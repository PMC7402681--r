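---
title: "Modelling E:I ratio and its spectral biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling E:I ratio and its spectral biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `eihurst`, the assumptions
they make, the free parameters that matter, and the design decisions taken
where the underlying methodology left genuine latitude. It states no
empirical result beyond what the package's own tests compute.

## The circuit model

The core object is a recurrent network of conductance-based leaky
integrate-and-fire neurons: 4000 excitatory (AMPA-like synapses) and 1000
inhibitory (GABA-like synapses) cells at full size, randomly connected with
probability 0.2 and no autapses. The membrane equation per neuron is

$$C_m \dot V = -g_L (V - V_L) - g_{AMPA}(t)(V - E_{AMPA}) - g_{GABA}(t)(V - E_{GABA}),$$

with an absolute refractory clamp at the reset potential after each spike
(synaptic conductances keep evolving during the refractory period).
Synaptic conductances follow difference-of-exponentials time courses
normalized to unit peak, with the receptor- and population-specific rise
and decay constants of the published reference parameter set for this
circuit family (AMPA decay 2 ms onto excitatory cells, 1 ms onto
inhibitory; GABA decay 5 ms onto both). `ei_ratio()` reads out
g = gI/gE as the ratio of the GABA to the recurrent-AMPA peak conductance
onto excitatory cells; the baseline values give g = 2.01/0.178 = 11.3, the
reference point of the model. `configure_ei_ratio()` rescales both GABA
conductances by a single common factor, leaving every AMPA conductance at
baseline, so experimental conditions are indexed by g alone.

Two external drives act on every neuron through `n_ext = 800` independent
AMPA synapses each: a thalamic drive, homogeneous Poisson at `nu0` spikes/s
per synapse (1.5 or 2 in the standard conditions), and an intracortical
drive whose rate follows a zero-mean Ornstein-Uhlenbeck process
(`ou_tau = 16` ms, `ou_sigma = 0.4 * nu0`) rectified at zero. The OU rate
is shared across the population by default (`ou_mode = "shared"`); a
per-neuron independent variant is available and makes the slow drive sum
incoherently in the field potential.

**Integration.** Conductance states decay exactly (exponential factors per
step), the membrane is advanced with forward Euler at `dt = 0.05` ms, and
recurrent spikes are delivered with a one-step delay (a configurable
latency ring buffer exists; the baseline latency is 0 as in the reference
table). External input events are discretized at the LFP sampling
resolution (1 kHz). A 50-neuron reduced network integrated at `dt/10` by an
independent brute-force R transcription of the same equations reproduces
the compiled integrator's spike trains to within 1 ms, which is the
package's correctness oracle for the dynamics.

**External-drive calibration.** The published table for this circuit
specifies per-synapse external conductances whose peak-normalized
difference-of-exponentials reading leaves every neuron roughly seventeen
standard deviations below threshold: taken literally, the network is
silent. The external-input implementation behind the reference parameter
set lives in prior simulation code and is not restated in the sources this
package follows, so the package treats the external pathway strength as a
calibration constant: `reduced_preset()` multiplies the thalamic and
intracortical conductances by `ext_scale = 7`, chosen once so that the
circuit sits in a stable fluctuation-driven state at the reference g
(excitatory rates of a few spikes per second that grow as g is lowered,
inhibition stabilizing the circuit). This is a property of the operating
point, not a fit to any downstream statistic.

**Reduced preset.** Tests and sweeps run a 500-neuron version (400 E,
100 I) with recurrent conductances scaled by the size ratio (x10), which
preserves the expected total recurrent conductance per neuron; preserving
per-neuron synapse *counts* is impossible at this size with a connection
probability at or below 1. The enlarged synaptic granularity makes
collective fluctuations stronger than at full size, which is the main
caveat when extrapolating reduced-preset results (see Limitations).
Sweeps use 10 s of activity per condition, the duration of the standard
protocol; onset transients are avoided by starting at rest and ramping the
external drive over the first 0.25 s (`ramp_s`), which keeps the circuit
out of a saturated high-rate attractor that coexists with the
fluctuation-driven state in parts of parameter space.

**The LFP proxy** is the sum of absolute values of the total AMPA and total
GABA synaptic currents on excitatory cells, including both external and
recurrent sources, sampled at 1 kHz. The absolute values reflect the
anatomical segregation of the two synapse types along dendrites, which
makes their current dipoles add with a common sign; the proxy is
non-negative by construction.

**Chemogenetic-style manipulations.** `apply_excitatory_dreadd()` lowers
the spike threshold of excitatory cells only (enhanced pyramidal
excitability, as with an excitatory DREADD); `apply_silencing_dreadd()`
lowers the leak potential of both populations (pan-neuronal silencing).
Both touch exactly one parameter so that sweeps isolate the manipulated
mechanism.

## Spectral biomarkers

`welch_psd()` averages Hamming-tapered, mean-removed periodograms over ten
segments with 50% overlap (both configurable); its normalization satisfies
Parseval's identity, which the tests check. `fit_piecewise_slopes()` fits
two independent least-squares lines to log10 power versus log10 frequency,
over 1-30 Hz and 30-100 Hz; the fits are exact on synthetic power laws and
invariant to rescaling the spectrum. `band_power_timecourse()` integrates
a sliding-window spectrogram over a band (1 s windows, 0.5 s steps at
1 kHz by default, which resolves alpha-band envelopes while leaving at
least a hundred points per 200-s trace); `lagged_band_bold_correlation()`
interpolates that time course to the BOLD sampling grid and reports the
Pearson correlation at each non-negative lag, with window-center
timestamps, so alignment is blurred by up to half a window.
`compute_falff()` uses a periodic Hamming taper and sums spectral
*amplitudes* (not powers) over 0.01-0.08 Hz relative to the detectable
band up to 0.25 Hz, excluding DC; for white noise the expected value is
the bandwidth ratio 0.28.

## Hurst exponent under the FIP model

The estimator models a series as a fractionally integrated process with
memory parameter d (H = d + 1/2), spectral density proportional to
$|2\sin(\pi f)|^{-2d}$. Per octave j of a decimated orthonormal Haar
transform, the model variance of the detail coefficients is the integral
of that density against the squared gain of the equivalent level-j detail
filter (computed on a midpoint frequency grid; the filter gains are exact,
not the ideal-bandpass approximation). Coefficients are treated as
independent within and across octaves — the standard wavelet-whitening
approximation — giving a Gaussian likelihood in which the scale parameter
profiles out in closed form; d is then found by a deterministic 25-point
grid multistart refined with bounded 1-D optimization inside
`d_bounds = c(-0.5, 1.5)` (hence H between 0 and 2; values above 1 mark
non-stationary series). The finest octave and octaves with fewer than 8
coefficients are dropped (`j_min = 2`, `j_max = floor(log2 n) - 3`)
because boundary and discretization bias concentrate there. Estimates are
invariant to affine transforms of the input. White noise is recovered at
H = 0.5 and a random walk at H = 1.5; across d in {0, 0.2, 0.4, 0.9} at
n = 4096 the mean absolute bias is below 0.01.

`simulate_fip()` draws exact stationary ARFIMA(0, d, 0) samples by
Davies-Harte circulant embedding of the closed-form autocovariance
(variance $\Gamma(1-2d)/\Gamma(1-d)^2$, lag recursion
$\rho_k = \rho_{k-1}(k-1+d)/(k-d)$); for d >= 0.5 it integrates an
ARFIMA(0, d-1, 0) path. An exact sampler matters here: truncated
moving-average filters converge slowly for d near 0.5 and visibly
under-dispersed in early versions. One subtlety the tests respect: the
*mean-subtracted* sample autocorrelation of a long-memory series is
negatively biased by order $n^{2d-1}$, so autocorrelation checks use the
non-centered estimator (the process mean is zero by construction).

`sliding_window_hurst()` applies the estimator over windows of 512 samples
(step 1 by default), the configuration used for dynamic BOLD analyses;
512 = 2^9 keeps the dyadic transform full-length.

## Forward model from LFP to BOLD

Ten-second traces are grouped by g (below 7.5, 7.5-11, above 11) and
concatenated in seeded random order, twenty at a time, into 200-s signals,
twenty repetitions per group. Frequencies below 1 Hz — which a 10-s trace
cannot constrain — are replaced by the log-log continuation of the fitted
low-frequency slope (mean over the source traces), anchored at the
signal's own spectral level just above 1 Hz, with uniformly drawn phases
under Hermitian symmetry and DC removed.

The BOLD transfer is applied in the frequency domain:
$\mathrm{FFT}(BOLD) = \mathrm{FFT}(LFP)\cdot|H_{hp}(f)|\cdot H_{hrf}(f) + \eta$.
The high-pass filter is the minimal two-parameter family meeting both
printed constraints — a second-order resonant high-pass whose natural
frequency and damping are solved numerically so the response peaks at
20 Hz and sits 3 dB below peak at 12.5 Hz (the cutoff convention is
relative to the peak). The HRF is either the canonical biphasic
double-gamma (peak 6 s, undershoot 16 s, ratio 1/6) or a biphasic
gamma-variate stand-in for the empirically derived kernel linking
gamma-band power to BOLD (peak 4 s by default); the empirical kernel's
functional form is not available, so the stand-in's parameters are
exposed. The noise term eta is complex, white, Hermitian-symmetric, and
defaults to 1e-4 of the median spectral amplitude; it represents
neurovascular variability faster than the acquisition. Content above 80%
of the output Nyquist frequency is removed in the spectral domain before
decimation to 0.5 Hz — an ideal anti-alias; an 8th-order IIR low-pass at a
2000-fold rate reduction would be numerically unusable, and the pipeline
is already in the frequency domain.

With eta = 0 the pipeline is exactly linear, and with white-noise input
the output spectrum is proportional to the squared combined transfer, both
of which the tests verify.

## Cohort statistics

`camouflage_score()` standardizes AQ, ADOS social-communication and RMET
within the autistic sample (mean-centering, then division by the maximum
possible score: 50, 22 and 36 by default — the ADOS maximum is the
module-4 social-communication algorithm total and is configurable since
instruments vary), forms CF1 = S_AQ - S_ADOS and CF2 = -S_RMET - S_ADOS,
and takes the first principal component of (CF1, CF2), sign-oriented so
that higher scores mean more camouflaging (positive correlation with
CF1 + CF2). The score is relative, not absolute, and is defined only for
the autistic sample because the ADOS is not administered to comparison
participants.

`enrichment_test()` builds the 2x2 membership table of two deduplicated,
case-normalized gene sets over a background count, reports the odds ratio
(0 or infinity with a flag when a margin is empty) and the one-tailed
over-representation p-value P(X >= overlap) from the hypergeometric
distribution; the tests verify it against exhaustive enumeration for
backgrounds up to 30.

`fisher_rz_compare()` is the standard two-sample comparison of
correlations through the variance-stabilizing transform, two-tailed.

`pls_group_contrast()` is non-rotated (contrast-driven) task PLS: the
cross-block matrix between the contrast and the group-mean parcel profiles
is decomposed by SVD (with a single contrast this is a normalized
projection; the code handles contrast matrices generally). Significance
comes from freely permuting subjects' group labels and recomputing the
singular value; parcel reliability from bootstrap ratios, with resampling
stratified within group and sign alignment of each bootstrap salience to
the original. The reported effect size standardizes the observed singular
value against the permutation null. The top 20% of parcels by absolute
bootstrap ratio form the reliability mask. Constant parcels are excluded
with a warning.

`generate_synthetic_cohort()` emulates a 2x2 sex-by-diagnosis cohort with
parcel-wise H values: Gaussian parcels (mean 1.0, SD 0.15 — the scale of
FIP-model H in resting BOLD), a planted interaction in a configurable
parcel subset (default shifts: autistic males down 1.3 SD, autistic
females up 0.27 SD), behavioral instruments generated from a latent
camouflaging trait, and a tunable coupling between that trait and the
first affected parcel in autistic females. Default group sizes are
29/23/33/25. What it does *not* emulate: spatial covariance between
parcels, motion or physiological confounds correlated with group, site or
acquisition effects, non-Gaussian score distributions, or missingness —
so passing recovery tests demonstrates the estimators' statistical
behavior under the planted structure, not robustness to real-data
artifacts.

## Problem sizes

The test-suite and acceptance computations use the 500-neuron reduced
preset at 10 s per condition with five seeds per condition; BOLD is
modelled from 200-s aggregates (100 samples at 0.5 Hz); estimator-recovery
studies use n = 4096 with 50 seeds; PLS studies use 200 permutations and
bootstraps over 20-30 synthetic cohorts. These sizes were chosen as the
smallest at which the quantities of interest stabilize against seed noise.

## Known limitations

* The reduced network's enlarged synapses strengthen collective
  fluctuations; its excitation-dominated states (g well below reference)
  are coherent high-rate oscillations rather than asynchronous fast
  states. In this implementation that inverts the expected flattening of
  the fitted 1/f slopes at low g, keeps the mild excitatory-threshold
  manipulation (and hence the excitation-driven fALFF drop) from going in
  the expected direction, breaks the rank correspondence between LFP-H and
  BOLD-H across the g grid (LFP-H is non-monotone in g with a mid-g
  maximum), leaves the gamma- and beta-band BOLD couplings statistically
  tied, and places the forward-modelled BOLD spectral peak near
  0.08-0.12 Hz rather than 0.03 Hz (the baseband BOLD spectrum scales as
  $f^{s+4}|H_{hrf}|^2$, so the peak position is set by the source's
  low-frequency slope s; at this circuit's reference slope of about -0.9
  no hemodynamically plausible kernel places the peak at 0.03 Hz). The
  corresponding acceptance checks are left failing rather than re-tuned;
  the H-versus-g direction, its plateau above the reference, the
  firing-rate ordering, the silencing control, and the gamma-over-alpha
  BOLD coupling do reproduce.
* The forward model is linear; it cannot produce negative coupling
  between low-frequency LFP power and BOLD.
* H estimates on 100-sample BOLD series rest on two octaves and are
  correspondingly noisy; windowed analyses want 512 samples.
* The sliding-window Hurst output is analysis-ready for mixed-effects
  modelling, but those models themselves (and mass-univariate GLM/FDR
  pipelines) are out of scope here.
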