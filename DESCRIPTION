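Package: crsim
Title: Coordinated Reset Stimulation of Plastic Hodgkin-Huxley Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a ring network of Hodgkin-Huxley neurons with
    Mexican-hat coupling and spike-timing-dependent plasticity (STDP), and
    delivers Coordinated Reset (CR) desynchronizing stimulation through
    equidistant sites with rapidly (RVS) or slowly (SVS-l) varying site
    sequences.  Implements the four-phase in-silico experiment
    (equilibration, STDP kindling, CR-on with m:n ON-OFF cycling, CR-off),
    the macroscopic outcome measures (sign-weighted mean synaptic weight,
    Kuramoto order parameter from linearly interpolated spike phases), and
    a stimulation-parameter sweep and statistics layer (boxplot summaries,
    rank-sum tests, frequency-ratio conversions) for mapping acute and
    long-lasting anti-kindling effects over stimulation frequency and
    intensity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
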