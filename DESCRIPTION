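Package: spinaltone
Title: Phasic and Tonic Inhibition Analysis for Spinal Interneuron Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the inhibitory control of spinal dorsal horn
    interneurons from in vitro recordings. Detects spontaneous postsynaptic
    currents in voltage-clamp traces and fits per-event decay kinetics to
    separate glycinergic, GABAergic and co-release events; estimates tonic
    inhibitory currents from all-points histograms of the holding current;
    measures rheobase, input resistance and resting potential from
    current-clamp protocols; converts GCaMP fluorescence to dF/F, calibrates
    a spiking threshold from paired current-injection data and calls
    somatostatin-evoked activity; and computes single-cell gene-expression
    prevalence in receptor-subunit panels. A synthetic-data engine generates
    every input type with retained ground truth for recovery testing, driven
    by a conductance-based leaky integrate-and-fire model with a switchable
    tonic chloride conductance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
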