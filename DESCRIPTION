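Package: stdpnet
Title: Feedforward Network Formation Under Asynchronous Stimulation and
    Spike-Timing-Dependent Plasticity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clock-driven simulation of two-dimensional, locally connected
    networks of leaky integrate-and-fire neurons whose synapses evolve under
    nearest-spike pair-based spike-timing-dependent plasticity (STDP) with
    hard bounds.  Provides the alternating paired-layer stimulation protocol
    that sculpts a feedforward structure out of an initially symmetric
    network, steady-current propagation tests of the trained structure,
    weight-distribution summaries, and exponential-falloff analyses that
    recover the STDP time constants from both the induced structural
    modification and the propagation dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'network.R'
    'dynamics.R'
    'protocols.R'
    'analysis.R'
    'config.R'
    'fixtures.R'
    'io.R'
    'stdp.R'
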