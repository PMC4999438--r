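Package: szgamma
Title: Multifactorial Modeling of Evoked Gamma Entrainment Deficits in an
    Auditory-Cortex Spiking Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based excitatory-inhibitory spiking network model of
    primary auditory cortex driven by 30 and 40 Hz click trains, with a
    six-dimensional sweep of GABAergic abnormalities (inhibitory decay times,
    connection counts and weights), simulated-EEG spectral analysis, three
    illness metrics scoring schizophrenia-like loss of 40 Hz entrainment,
    normalized mutual information between parameter subsets and the network
    phenotype, surrogate band-power generators for fast pipeline validation,
    and a mixed-design ANOVA with Greenhouse-Geisser correction for group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
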