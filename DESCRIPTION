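Package: lsoif
Title: Integrate-and-Fire Models of Lateral Superior Olive Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for six single-compartment integrate-and-fire
    (IF) type models of lateral superior olive (LSO) neurons in the auditory
    brainstem: passive and active (low-voltage-activated potassium) membranes,
    each with threshold-reset, spike-mimicking-current, or exponential spike
    generation. Provides the common synaptic input stage (inhomogeneous
    Poisson afferent trains with von Mises phase locking, alpha-function
    conductances), binaural phase-difference and interaural-level-difference
    tuning experiments, monaural amplitude-modulation frequency tuning,
    physiological response criteria scoring, interspike-interval statistics
    (histograms, hazard rates, conditional means), subthreshold
    characterization (I-V curves, impedance spectra, postsynaptic
    potentials), and parameter calibration utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
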