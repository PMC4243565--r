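Package: RecurrentInfomax
Title: Recurrent-Network Infomax Learning with Locally Computable Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for stochastic binary recurrent
    neural networks trained by a biologically plausible information-maximization
    rule: per-synapse eligibility traces gated by global modulatory signals.
    Includes the stimulus protocols (episodic external sequences, whitened
    natural-image patches through ON/OFF encoders) and the spike-train readouts
    (Gaussian mutual-information estimates, exact enumeration for tiny networks,
    neuronal-avalanche statistics, precise firing-sequence censuses,
    autocorrelograms, spike-triggered-average receptive fields, strong-chain
    extraction) used to characterize the emergent dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
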