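Package: waveclamp
Title: Wavelet-Based Voltage-Clamp Protocol Design for Ion-Channel Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-cell ionic currents of Markov gating models of the
    Shaker potassium channel under arbitrary voltage waveforms, synthesizes
    fluctuating voltage-clamp pulses as superpositions of dyadic wavelets
    (Haar and Daubechies-8), and optimizes the wavelet coefficients with a
    genetic algorithm to maximize a chi-squared divergence between the currents
    predicted by competing models (model discrimination) or the occupancy of a
    chosen conformational state (kinetic focusing). Ships the four published
    Shaker gating schemes (ZHA A, ZHA D, BPS, SS) as a parameter registry,
    builds standard activation and tail step protocols for comparison, and
    provides import/export of current traces and stimulus waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
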