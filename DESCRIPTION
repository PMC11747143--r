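Package: oysterthresh
Title: Low-Salinity Exposure Thresholds for Eastern Oyster Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects low-salinity exposure thresholds for eastern oyster
    (Crassostrea virginica) populations from daily station salinity series and
    dredge abundance monitoring. Computes run-length exposure covariates (total
    and maximum consecutive days within salinity bins over summer or calendar
    windows), fits a hierarchical Bayesian normal model with nested
    station-in-basin and year intercepts by a conjugate Gibbs sampler, compares
    model scales by DIC and posterior predictive loss, sweeps fitted models
    against a critical abundance (half the five-year mean) to derive day-count
    thresholds, and runs a parallel random-forest branch that converts partial
    dependence changepoints into thresholds via a subtract-from-window rule. A
    synthetic-data generator emulating the station/basin/year monitoring
    structure makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
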