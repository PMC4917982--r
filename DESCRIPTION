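Package: rootcap
Title: Benchmarking Electrical Impedance Variables for Root Biomass Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating plant root dry mass from electrical
    impedance spectra. Converts magnitude/phase spectra into the candidate
    electrical variables of the equivalent serial and parallel RC circuits
    (capacitances, resistances, conductance, impedance, reactance, phase),
    screens each variable's linear relation with root dry mass across the
    injected-current frequency sweep, ranks predictors with a sensitivity
    score that penalises intercept-dominated regressions, compares stem
    electrode types with paired signed-rank tests, recomputes sensitivity
    scores for published capacitance-root mass regressions, and provides a
    plant-soil equivalent-circuit simulator so the whole pipeline can be
    exercised on synthetic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
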