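Package: dendrofluct
Title: Analytic Dendritic Integration in the Fluctuation-Driven Regime
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-neuron computation in the fluctuation-driven
    regime. A symmetric Rall-branched passive dendrite plus lumped soma is
    driven by synchrony-biased compound Poisson synaptic input; cable theory
    and shotnoise calculus give closed-form estimates of the somatic
    membrane-potential fluctuation statistics (mean, amplitude, and
    autocorrelation time) together with the somatic input-conductance ratio.
    The package also provides the somatic input-impedance model and its
    grid-based passive-parameter fit, curated presynaptic stimulation
    protocols with an inhibitory balance solver, a ground-truth implicit
    compartmental simulator of the full branched tree, and
    phenomenological-threshold firing-response functions for population
    coupling analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
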