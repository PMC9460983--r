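Package: peatflow
Title: Waterlogging-Aware Modelling of Tree Transpiration from Water Table Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hierarchical modelling of daily tree transpiration in
    peatland stands where the water table moves between waterlogged,
    optimal and dry regimes. Links water table depth to soil water
    content through a van Genuchten retention curve, to soil-to-root
    hydraulic conductance through a segmented (non-monotonic) response
    capturing both hypoxic and drought limitation, and to stomatal
    behaviour through a marginal water-use efficiency bridge into an
    optimal-stomata canopy model. Provides Bayesian calibration by
    differential-evolution MCMC with a heteroscedastic error model,
    reference-model comparison, evaluation statistics, and a synthetic
    data generator for testing identifiability.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
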