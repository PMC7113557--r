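Package: pasrat
Title: Simulation and Analysis of Paired Associative Stimulation in Freely
    Behaving Rats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico reimplementation of a paired associative stimulation
    (PAS) experiment in freely behaving rats. Provides a synthetic corticospinal
    plant with configurable spike timing-dependent plasticity (STDP), a
    closed-loop EMG-triggered cortical stimulation probe for assessing
    corticomotor excitability, motor evoked potential (MEP) screening and
    quantification by peak-to-peak and rectified-integral methods, the
    interstimulus-interval to synaptic-timing design calculus at the spinal and
    cortical levels, and the repeated-measures mixed-model analysis of
    normalized MEP ratios, so that both a null world (no plasticity) and
    STDP-positive counterfactuals can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
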