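Package: eihurst
Title: Excitation-Inhibition Ratio Biomarkers from Simulated Neural Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the synaptic excitation-inhibition (E:I) ratio of a
    local cortical circuit to spectral biomarkers measurable in field-potential
    and fMRI BOLD time series. Provides a conductance-based leaky
    integrate-and-fire recurrent network simulator with an LFP proxy, a
    frequency-domain forward model from LFP to BOLD, wavelet maximum-likelihood
    estimation of the Hurst exponent under a fractionally integrated process
    model, piecewise 1/f slope fitting, fALFF, chemogenetic-style parameter
    sweeps, and cohort-level statistics (camouflaging score, gene-set
    enrichment, Fisher r-to-z comparison, contrast partial least squares) with
    a synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
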