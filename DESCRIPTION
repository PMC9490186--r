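Package: clonalfx
Title: Two-Generation Growth Simulation of Parental Nitrogen Effects in
    Clonal Plants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates parental environmental effects driven by resource
    provisioning in clonal plants such as Alternanthera philoxeroides. Couples
    deterministic logistic growth with a nitrogen-dependent carrying capacity,
    power-law allometry linking parental biomass to the number and mean mass of
    vegetative propagules, Weibull-distributed propagule sizes, and survival
    thinning into a two-generation (parent-offspring) engine. Provides growth-model
    selection by AIC among six classic curve families, per-plant size-distribution
    selection by the Cramer-von Mises statistic, full factorial simulation
    experiments with sequential (Type-I) ANOVA of the design factors, and a
    synthetic greenhouse-data generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
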