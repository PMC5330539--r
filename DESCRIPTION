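Package: critcap
Title: Criticality and Cost-Efficient Information Capacity in
    Excitatory-Inhibitory Spiking Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates conductance-based excitatory-inhibitory networks of
    leaky integrate-and-fire neurons with bi-exponential synaptic kernels,
    and characterises the resulting spike rasters across scales: inter-spike
    interval irregularity, pairwise synchrony, population oscillations and
    their spectral peak, and neuronal avalanches with a discrete power-law
    fit and a distance-to-power-law statistic. Windowed population spike
    patterns are scored for information capacity (plug-in entropy), energy
    cost and energy efficiency, and compared against the closed-form
    maximum-entropy optimum for binary and analog coding scenarios,
    including a decomposition of the efficiency gap into burst and
    synchronisation reductions. Seeded surrogate generators (Poisson,
    gamma-renewal, jittered-synchrony, branching-process rasters) and a
    parameter-sweep driver over synaptic decay times complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
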