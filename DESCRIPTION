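Package: jrconnect
Title: Structure-Function Coupling in Jansen-Rit Neural Mass Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of Jansen-Rit neural mass models coupled by
    a weighted structural connectome, estimates functional connectivity from
    instantaneous phases (mean phase coherence and mean phase agreement), and
    explains the structure-function map across the excitation/inhibition
    parameter plane by linear stability analysis of network equilibria,
    false-bifurcation (waveform inflection) detection, and a weakly coupled
    oscillator phase reduction whose synchrony Jacobian yields a cheap
    eigenmode predictor of functional connectivity. Includes a generator of
    modular surrogate connectomes so the full pipeline runs without
    neuroimaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
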