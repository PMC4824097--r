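Package: gatedscanner
Title: Gated-Scanner Simulation and Analysis of Chi Recognition by a
    Translocating Helicase-Nuclease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of the two-state gated-scanner model of
    recombination-hotspot (Chi) recognition by the bacterial AddAB
    helicase-nuclease, together with the analysis pipelines used to
    characterise it: pause detection and censored dwell-time statistics for
    magnetic-tweezers translocation traces, exponential-decay fitting of
    exonuclease-chase dissociation time courses, biphasic offset-exponential
    fitting of triplex-displacement stopped-flow transients with Chi-dose and
    distance-series inversions, and Chi-fragment yield fold-changes. Packaged
    parameter sets describe wild-type and mutant (latch and Chi-binding)
    enzyme variants, and seeded scenario configurations reproduce the
    ensemble and single-molecule observables end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
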